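#' Triangle surface mesh
#'
#' Constructs an oriented triangle mesh in millimetres, the package's common
#' geometry container (STL-compatible). Degenerate (zero-area) faces are
#' dropped at construction and the `closed` flag is computed from the
#' edge-sharing test: a mesh is closed iff every undirected edge is shared by
#' exactly two faces.
#'
#' @param vertices numeric matrix, one row per vertex, columns x, y, z (mm).
#' @param faces integer matrix, one row per triangle, vertex indices
#'   (1-based), counter-clockwise when viewed from outside.
#' @return An object of class `surface_mesh`: list with `vertices`, `faces`,
#'   `closed`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns (x, y, z)")
  if (!all(is.finite(vertices))) stop("vertices contain non-finite coordinates")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns")
  if (nrow(faces) < 1L) stop("mesh has no faces")
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range")
  a2 <- face_areas2(vertices, faces)
  keep <- a2 > (1e-12)^2   # squared doubled area; zero-area faces dropped
  faces <- faces[keep, , drop = FALSE]
  if (nrow(faces) < 1L) stop("mesh has no non-degenerate faces")
  structure(list(vertices = vertices, faces = faces,
                 closed = mesh_is_closed(vertices, faces)),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces, %s\n",
              nrow(x$vertices), nrow(x$faces),
              if (isTRUE(x$closed)) "closed" else "open"))
  invisible(x)
}

# squared doubled triangle areas |(b-a) x (c-a)|^2, vectorized
face_areas2 <- function(v, f) {
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  e1 <- b - a; e2 <- c - a
  nx <- e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L]
  ny <- e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L]
  nz <- e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]
  nx * nx + ny * ny + nz * nz
}

#' Per-facet areas of a mesh (mm^2)
#' @param mesh a `surface_mesh`.
#' @return numeric vector, one area per face.
#' @export
facet_areas <- function(mesh) {
  sqrt(face_areas2(mesh$vertices, mesh$faces)) / 2
}

# undirected edge keys for all 3n face edges; nv vertices
edge_keys <- function(faces, nv) {
  i <- c(faces[, 1L], faces[, 2L], faces[, 3L])
  j <- c(faces[, 2L], faces[, 3L], faces[, 1L])
  lo <- pmin(i, j); hi <- pmax(i, j)
  as.numeric(lo) * (nv + 1) + as.numeric(hi)  # exact in doubles up to ~2^53
}

# every undirected edge shared by exactly two faces?
mesh_is_closed <- function(vertices, faces) {
  k <- edge_keys(faces, nrow(vertices))
  tab <- table_counts(k)
  all(tab == 2L)
}

# counts of repeated keys without the overhead of table()
table_counts <- function(k) {
  k <- sort(k)
  brk <- c(TRUE, diff(k) != 0)
  grp <- cumsum(brk)
  tabulate(grp)
}

# directed-edge consistency: each undirected edge must be traversed once in
# each direction by its two faces (orientability + consistent winding)
mesh_orientation_consistent <- function(mesh) {
  nv <- nrow(mesh$vertices)
  f <- mesh$faces
  i <- c(f[, 1L], f[, 2L], f[, 3L])
  j <- c(f[, 2L], f[, 3L], f[, 1L])
  dir_keys <- as.numeric(i) * (nv + 1) + as.numeric(j)
  !anyDuplicated(dir_keys)
}

# deduplicate vertex rows within tolerance; returns list(vertices, map)
# map[i] = new index of old vertex i
dedup_vertices <- function(v, tol = 1e-6) {
  key <- round(v / tol)
  o <- do.call(order, list(key[, 1L], key[, 2L], key[, 3L]))
  ks <- key[o, , drop = FALSE]
  new_grp <- c(TRUE, rowSums(ks[-1L, , drop = FALSE] !=
                             ks[-nrow(ks), , drop = FALSE]) > 0)
  grp_sorted <- cumsum(new_grp)
  grp <- integer(nrow(v))
  grp[o] <- grp_sorted
  first_idx <- o[new_grp]   # representative old index per group
  list(vertices = v[first_idx, , drop = FALSE], map = grp)
}

#' Volume enclosed by a closed triangle mesh (mm^3)
#'
#' Signed-tetrahedron (divergence theorem) volume
#' \eqn{V = |\sum_f v_1 \cdot (v_2 \times v_3)| / 6} over all faces.
#' The mesh must be closed; surface meshes straight from segmentation that are
#' not watertight cannot be assigned a volume.
#'
#' @param mesh a closed `surface_mesh`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  if (!isTRUE(mesh$closed)) stop("mesh_volume requires a closed mesh")
  abs(mesh_signed_volume(mesh))
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1L], , drop = FALSE]
  b <- v[f[, 2L], , drop = FALSE]
  c <- v[f[, 3L], , drop = FALSE]
  sum(a[, 1L] * (b[, 2L] * c[, 3L] - b[, 3L] * c[, 2L]) +
      a[, 2L] * (b[, 3L] * c[, 1L] - b[, 1L] * c[, 3L]) +
      a[, 3L] * (b[, 1L] * c[, 2L] - b[, 2L] * c[, 1L])) / 6
}

#' Ratio of smoothed to original enclosed volume
#'
#' @param orig,smoothed closed `surface_mesh` objects.
#' @return `mesh_volume(smoothed) / mesh_volume(orig)` (dimensionless).
#' @export
volume_ratio <- function(orig, smoothed) {
  v0 <- mesh_volume(orig)
  if (v0 <= 0) stop("original mesh has zero volume")
  mesh_volume(smoothed) / v0
}

# flip winding so the signed volume is positive (outward normals) for a
# closed, consistently oriented mesh
orient_outward <- function(mesh) {
  if (mesh_signed_volume(mesh) < 0)
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L), drop = FALSE]
  mesh
}
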