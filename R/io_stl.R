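#' Read an STL surface mesh
#'
#' Reads ASCII or binary STL (autodetected). Vertices repeated across facets
#' are merged within a tolerance of 1e-6 mm (far below the ~0.7 mm voxel scale
#' of the images this package targets), and the `closed` flag is recomputed
#' from the edge-sharing test.
#'
#' @param path path to an `.stl` file.
#' @return a [surface_mesh()].
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 15) stop("malformed STL: file too small")
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", n = min(sz, 512))
  is_ascii <- identical(rawToChar(head_raw[1:5]), "solid") &&
    grepl("facet", rawToChar(head_raw[head_raw != as.raw(0)]),
          fixed = TRUE, useBytes = TRUE)
  close(con); on.exit()
  tri <- if (is_ascii) read_stl_ascii(path) else read_stl_binary(path, sz)
  if (nrow(tri) == 0L) stop("empty STL: no facets")
  dd <- dedup_vertices(tri, tol = 1e-6)
  faces <- matrix(dd$map, ncol = 3L, byrow = TRUE)
  surface_mesh(dd$vertices, faces)
}

# binary layout: 80-byte header, uint32 count, then 50-byte records
# (normal 3f, vertices 9f, 2-byte attribute)
read_stl_binary <- function(path, sz) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80)
  n <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  if (is.na(n) || n < 0) stop("malformed STL: bad triangle count")
  if (sz != 84 + 50 * as.numeric(n))
    stop("malformed STL: size does not match triangle count")
  if (n == 0L) stop("empty STL: no facets")
  body <- readBin(con, "raw", n = 50 * n)
  rec0 <- rep(seq.int(0L, by = 50L, length.out = n), each = 48L)
  idx <- rec0 + rep.int(1:48, n)
  vals <- readBin(body[idx], "double", n = 12 * n, size = 4, endian = "little")
  m <- matrix(vals, ncol = 12L, byrow = TRUE)   # nx ny nz v1 v2 v3
  v <- m[, 4:12, drop = FALSE]
  tri <- matrix(t(v), ncol = 3L, byrow = TRUE)  # rows v1,v2,v3 per facet
  if (!all(is.finite(tri))) stop("malformed STL: non-finite vertex")
  tri
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, perl = TRUE, value = TRUE)
  if (length(vl) == 0L) stop("empty STL: no facets")
  if (length(vl) %% 3L != 0L) stop("malformed STL: vertex count not multiple of 3")
  nums <- scan(text = sub("^\\s*vertex\\s+", "", vl), quiet = TRUE)
  if (length(nums) != 3L * length(vl)) stop("malformed STL: bad vertex line")
  tri <- matrix(nums, ncol = 3L, byrow = TRUE)
  if (!all(is.finite(tri))) stop("malformed STL: non-finite vertex")
  tri
}

#' Write a surface mesh to STL
#'
#' Binary output is bit-stable for a fixed mesh: 80-byte header, little-endian
#' 32-bit triangle count, then one 50-byte record per facet.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @param dialect `"binary"` (default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, dialect = c("binary", "ascii")) {
  dialect <- match.arg(dialect)
  v <- mesh$vertices; f <- mesh$faces
  if (is.null(f) || nrow(f) == 0L) stop("refusing to write a mesh with zero faces")
  if (!all(is.finite(v))) stop("mesh has non-finite vertex coordinates")
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  cc <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
             e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
             e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  len <- sqrt(rowSums(n * n))
  len[len == 0] <- 1
  n <- n / len
  if (dialect == "binary") {
    con <- file(path, "wb")
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "vesselsmooth binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    rec <- t(cbind(n, a, b, cc))          # 12 floats per facet, column-per-facet
    flt <- writeBin(as.numeric(rec), raw(), size = 4, endian = "little")
    fm <- matrix(flt, nrow = 48L)
    out <- rbind(fm, matrix(as.raw(0), nrow = 2L, ncol = ncol(fm)))
    writeBin(as.vector(out), con)
  } else {
    fmt_v <- function(m) sprintf("      vertex %.9g %.9g %.9g",
                                 m[, 1L], m[, 2L], m[, 3L])
    txt <- c("solid vesselsmooth",
             as.vector(rbind(
               sprintf("  facet normal %.9g %.9g %.9g", n[, 1L], n[, 2L], n[, 3L]),
               "    outer loop",
               fmt_v(a), fmt_v(b), fmt_v(cc),
               "    endloop",
               "  endfacet")),
             "endsolid vesselsmooth")
    writeLines(txt, path)
  }
  invisible(path)
}
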