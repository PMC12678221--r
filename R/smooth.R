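#' Align contour indices across a stack of sections
#'
#' Establishes generator-line correspondence: each section's start index is
#' cyclically shifted (and its orientation reversed if needed) to minimize
#' the sum of squared distances to the previous, already-aligned section.
#' The first section is anchored with index 1 at the +y direction from its
#' centroid. Shift search uses the FFT cross-correlation of the complex
#' contour y + iz, equivalent to the exhaustive search.
#'
#' @param sections list of N x 2 contours (equal N), ordered along the part.
#' @return list with `sections` (aligned contours), `shifts`, `reversed`.
#' @export
align_generators <- function(sections) {
  N <- nrow(sections[[1L]])
  if (any(vapply(sections, nrow, 1L) != N))
    stop("sections have mismatched point counts")
  rot <- function(p, s) if (s == 0L) p else
    p[c((s + 1L):N, 1L:s), , drop = FALSE]
  rev_ring <- function(p) p[c(1L, N:2L), , drop = FALSE]
  # anchor: start index at the +y direction from the centroid
  p1 <- sections[[1L]]
  ctr <- colMeans(p1)
  ang <- atan2(p1[, 2L] - ctr[2L], p1[, 1L] - ctr[1L])
  start <- which.min(abs(ang))
  out <- vector("list", length(sections))
  out[[1L]] <- rot(p1, start - 1L)
  shifts <- integer(length(sections)); shifts[1L] <- start - 1L
  reversed <- logical(length(sections))
  if (length(sections) > 1L) {
    for (k in 2:length(sections)) {
      b <- complex(real = out[[k - 1L]][, 1L],
                   imaginary = out[[k - 1L]][, 2L])
      fb <- Conj(stats::fft(b))
      best <- c(-Inf, 0L, FALSE)
      for (rv in c(FALSE, TRUE)) {
        p <- if (rv) rev_ring(sections[[k]]) else sections[[k]]
        a <- complex(real = p[, 1L], imaginary = p[, 2L])
        cc <- Re(stats::fft(stats::fft(a) * fb, inverse = TRUE)) / N
        s <- which.max(cc)
        if (cc[s] > best[1L]) best <- c(cc[s], s - 1L, rv)
      }
      p <- if (best[3L]) rev_ring(sections[[k]]) else sections[[k]]
      out[[k]] <- rot(p, as.integer(best[2L]))
      shifts[k] <- as.integer(best[2L]); reversed[k] <- as.logical(best[3L])
    }
  }
  list(sections = out, shifts = shifts, reversed = reversed)
}

#' Smooth a vessel point cloud into a watertight surface
#'
#' Full noise-reduction pipeline for lumen surfaces from low-resolution
#' images: partition into parts, map points onto y-z planes, resample each
#' contour at equal arc spacing `dL`, align generator indices, apply the
#' selective sigma/median filter once to each generator line's y and z
#' reference-point sequences, interpolate the filtered generators with
#' natural cubic splines, evaluate densely at `step`, and loft the result
#' (and, for reference, the unsmoothed sections) back to closed triangle
#' meshes. Part4 (the bifurcation mixing zone) is excluded from the loft
#' sections; the junction is closed with a watertight zipper stitch between
#' the last parent contour and the two first branch contours.
#'
#' The filter judges each reference point against the mean +/- q sigma of
#' its `m` neighbouring reference points on either side (about `m * dx`
#' millimetres along the vessel), which is what lets it catch noise at the
#' image-voxel wavelength; `filter_domain = "dense"` instead filters the
#' densely evaluated spline curves, where the same window spans only
#' `m * step` mm and acts on far smaller scales.
#'
#' @param cloud a [raw_point_cloud()].
#' @param dL contour resampling arc spacing (mm).
#' @param step dense longitudinal sampling step (mm).
#' @param q,m,passes noise-filter parameters, see [noise_filter_series()].
#' @param filter_domain `"knots"` (filter the reference points, then fit the
#'   splines) or `"dense"` (fit splines first, filter the dense samples).
#' @param part4_buffer_k Part4 half-width in slices.
#' @param linking_factor slice component linking distance in units of dx.
#' @return object of class `vessel_smooth`: `mesh` (smoothed, closed),
#'   `raw_mesh` (loft of the unsmoothed sections), `curves` /`curves_raw`
#'   (per-part generator curves: `x`, `Y`, `Z`), `loft_index` /
#'   `loft_index_raw` (per-part section-by-generator vertex index maps),
#'   `altered_fraction` (share of dense samples edited by the filter),
#'   `bifurcation` (see [find_bifurcation_point()]; `NULL` for unbranched
#'   vessels), `partition`, `params`.
#' @export
smooth_vessel <- function(cloud, dL = 0.1, step = 0.1, q = 1, m = 2,
                          passes = 1,
                          filter_domain = c("knots", "dense"),
                          part4_buffer_k = 3, linking_factor = 1.5) {
  filter_domain <- match.arg(filter_domain)
  pg <- partition_geometry(cloud, part4_buffer_k, linking_factor)
  flipped <- FALSE
  if (!is.na(pg$topology_change_x)) {
    two_lo <- pg$ncomp[which.min(pg$slice_x)] == 2L
    if (isTRUE(two_lo)) {     # branches at low x: mirror so the parent leads
      flipped <- TRUE
      cloud$points[, 1L] <- -cloud$points[, 1L]
      pg <- partition_geometry(cloud, part4_buffer_k, linking_factor)
    }
  }
  dx <- cloud$slice_spacing_dx
  tcx <- pg$topology_change_x
  in_buffer <- function(x) !is.na(tcx) &
    abs(x - tcx) <= part4_buffer_k * dx + 1e-9
  collect_sections <- function(slice_sel, branch_id = NA) {
    secs <- list()
    for (k in slice_sel) {
      idx <- which(pg$slice_id == pg$slices[k])
      if (!is.na(branch_id)) idx <- idx[pg$branch[idx] == branch_id]
      if (length(idx) < 3L) next
      secs[[length(secs) + 1L]] <-
        list(x = pg$slice_x[k], yz = cloud$points[idx, 2:3, drop = FALSE])
    }
    secs
  }
  resample_part <- function(secs) {
    if (length(secs) < 2L) stop("too few usable sections in a part")
    per <- vapply(secs, function(s) contour_perimeter(s$yz), 0)
    N <- max(3L, as.integer(round(stats::median(per) / dL)))
    out <- list()
    for (s in secs) {
      pts <- tryCatch(resample_contour(s$yz, dL, n_points = N),
                      error = function(e) NULL)
      if (is.null(pts)) {
        warning(sprintf("dropping degenerate section at x = %.3g", s$x))
        next
      }
      out[[length(out) + 1L]] <- list(x = s$x, pts = pts)
    }
    if (length(out) < 2L) stop("too few usable sections in a part")
    al <- align_generators(lapply(out, `[[`, "pts"))
    for (i in seq_along(out)) out[[i]]$pts <- al$sections[[i]]
    out
  }
  one_comp <- which(pg$ncomp == 1L & !in_buffer(pg$slice_x))
  parts <- list(Part1 = resample_part(collect_sections(one_comp)))
  if (!is.na(tcx)) {
    two_comp <- which(pg$ncomp == 2L & !in_buffer(pg$slice_x))
    parts$Part2 <- resample_part(collect_sections(two_comp, 1L))
    parts$Part3 <- resample_part(collect_sections(two_comp, 2L))
  }
  knot_rings <- function(secs)
    lapply(secs, function(s) cbind(s$x, s$pts))
  curves_raw <- lapply(parts, function(secs) {
    list(x = vapply(secs, `[[`, 0, "x"),
         Y = do.call(rbind, lapply(secs, function(s) s$pts[, 1L])),
         Z = do.call(rbind, lapply(secs, function(s) s$pts[, 2L])))
  })
  # dense smoothed generator curves
  n_changed <- 0; n_total <- 0
  filter_mat <- function(M) {
    if (nrow(M) < 2 * m + 1) {
      warning("part shorter than the filter window: left unfiltered")
      return(M)
    }
    Mf <- M
    for (g in seq_len(ncol(M)))
      Mf[, g] <- noise_filter_series(M[, g], q = q, m = m, passes = passes)
    n_changed <<- n_changed + sum(Mf != M)
    n_total <<- n_total + length(M)
    Mf
  }
  curves <- lapply(parts, function(secs) {
    if (filter_domain == "knots") {
      xs <- vapply(secs, `[[`, 0, "x")
      Yf <- filter_mat(do.call(rbind, lapply(secs, function(s) s$pts[, 1L])))
      Zf <- filter_mat(do.call(rbind, lapply(secs, function(s) s$pts[, 2L])))
      secs <- lapply(seq_along(secs), function(j)
        list(x = xs[j], pts = cbind(Yf[j, ], Zf[j, ])))
      gss <- fit_slice_splines(secs)
      dense <- evaluate_splines(gss, step)
      list(x = dense$x, Y = dense$Y, Z = dense$Z)
    } else {
      gss <- fit_slice_splines(secs)
      dense <- evaluate_splines(gss, step)
      list(x = dense$x, Y = filter_mat(dense$Y), Z = filter_mat(dense$Z))
    }
  })
  dense_rings <- function(cv)
    lapply(seq_along(cv$x), function(j) cbind(cv$x[j], cv$Y[j, ], cv$Z[j, ]))
  build <- function(ring_sets) {
    if (length(ring_sets) == 1L) {
      mesh <- ring_tube_mesh(ring_sets[[1L]])
    } else {
      mesh <- pants_mesh(ring_sets[[1L]], ring_sets[[2L]], ring_sets[[3L]])
    }
    vmap <- attr(mesh, "vertex_map")
    idx <- list(); base <- 0L
    for (p in seq_along(ring_sets)) {
      S <- length(ring_sets[[p]]); N <- nrow(ring_sets[[p]][[1L]])
      idx[[p]] <- matrix(vmap[base + seq_len(S * N)], nrow = S, ncol = N,
                         byrow = TRUE)
      base <- base + S * N
    }
    names(idx) <- names(parts)
    list(mesh = mesh, index = idx)
  }
  raw_rings <- lapply(parts, knot_rings)
  raw_built <- build(unname(raw_rings))
  sm_built <- build(unname(lapply(curves, dense_rings)))
  bif <- NULL
  if (!is.na(tcx)) {
    p4 <- cloud$points[pg$part == "Part4", , drop = FALSE]
    # the first planes where the branches exist: the earliest
    # two-component slice (inside the Part4 buffer)
    k1 <- min(which(pg$ncomp == 2L))
    idx1 <- which(pg$slice_id == pg$slices[k1])
    s2 <- cloud$points[idx1[pg$branch[idx1] == 1L], , drop = FALSE]
    s3 <- cloud$points[idx1[pg$branch[idx1] == 2L], , drop = FALSE]
    bif <- tryCatch(find_bifurcation_point(s2, s3, p4),
                    error = function(e) NULL)
  }
  res <- list(mesh = sm_built$mesh, raw_mesh = raw_built$mesh,
              curves = curves, curves_raw = curves_raw,
              loft_index = sm_built$index, loft_index_raw = raw_built$index,
              altered_fraction = n_changed / max(n_total, 1),
              bifurcation = bif, partition = pg, flipped = flipped,
              params = list(dL = dL, step = step, q = q, m = m,
                            passes = passes, filter_domain = filter_domain,
                            part4_buffer_k = part4_buffer_k))
  if (flipped) {
    res$mesh$vertices[, 1L] <- -res$mesh$vertices[, 1L]
    res$mesh <- orient_outward(res$mesh)
    res$raw_mesh$vertices[, 1L] <- -res$raw_mesh$vertices[, 1L]
    res$raw_mesh <- orient_outward(res$raw_mesh)
    for (p in seq_along(res$curves)) {
      res$curves[[p]]$x <- -res$curves[[p]]$x
      res$curves_raw[[p]]$x <- -res$curves_raw[[p]]$x
    }
    if (!is.null(res$bifurcation)) {
      res$bifurcation$point[1L] <- -res$bifurcation$point[1L]
      res$bifurcation$p2[1L] <- -res$bifurcation$p2[1L]
      res$bifurcation$p3[1L] <- -res$bifurcation$p3[1L]
    }
  }
  class(res) <- "vessel_smooth"
  res
}

#' @export
print.vessel_smooth <- function(x, ...) {
  cat(sprintf(paste0("vessel_smooth: %d parts, %d smoothed vertices, ",
                     "%.1f%% of samples edited\n"),
              length(x$curves), nrow(x$mesh$vertices),
              100 * x$altered_fraction))
  invisible(x)
}

#' Smoothed watertight surface of a vessel point cloud
#'
#' Convenience wrapper around [smooth_vessel()] returning only the final
#' smoothed mesh.
#'
#' @inheritParams smooth_vessel
#' @return a closed [surface_mesh()].
#' @export
smooth_geometry <- function(cloud, dL = 0.1, step = 0.1, q = 1, m = 2,
                            passes = 1,
                            filter_domain = c("knots", "dense"),
                            part4_buffer_k = 3, linking_factor = 1.5) {
  smooth_vessel(cloud, dL, step, q, m, passes, filter_domain,
                part4_buffer_k, linking_factor)$mesh
}

#' Rebuild generator curves from a displaced loft mesh
#'
#' After moving the vertices of a lofted mesh (e.g. with [taubin_smooth()]),
#' this recovers the per-part generator curves through the loft's
#' section-by-generator index map so that [geometry_roughness()] can score
#' the displaced surface. `X` is returned as a per-vertex matrix because
#' vertex x positions are no longer shared across a ring.
#'
#' @param mesh a loft mesh whose vertex order is unchanged.
#' @param loft_index per-part index maps from [smooth_vessel()]
#'   (`loft_index` or `loft_index_raw`).
#' @return list of per-part curve sets (`X`, `Y`, `Z` matrices).
#' @export
curves_from_mesh <- function(mesh, loft_index) {
  lapply(loft_index, function(idx) {
    list(X = matrix(mesh$vertices[idx, 1L], nrow(idx), ncol(idx)),
         Y = matrix(mesh$vertices[idx, 2L], nrow(idx), ncol(idx)),
         Z = matrix(mesh$vertices[idx, 3L], nrow(idx), ncol(idx)))
  })
}
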