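#' Partition a vessel point cloud into four parts
#'
#' Points are grouped into image slices along x, each slice is split into
#' connected components in the y-z plane (single linkage, linking distance
#' `1.5 * dx`), and labels are assigned: slices with one component upstream
#' of the topology change are `Part1`, two-component slices form the two
#' branches `Part2` / `Part3` (tracked by centroid continuity), and all
#' points within `k * dx` of the topology-change slice are relabelled
#' `Part4`, the mixing zone around the bifurcation.
#'
#' @param cloud a [raw_point_cloud()].
#' @param part4_buffer_k half-width of the Part4 buffer, in slices.
#' @param linking_factor component linking distance as a multiple of `dx`.
#' @return object of class `partitioned_geometry`: `part` (factor per point),
#'   `topology_change_x` (`NA` when the vessel does not branch), `slice_id`,
#'   `slice_x`, `branch` (1/2 for two-component slices, `NA` otherwise).
#' @export
partition_geometry <- function(cloud, part4_buffer_k = 3,
                               linking_factor = 1.5) {
  pts <- cloud$points
  dx <- cloud$slice_spacing_dx
  if (nrow(pts) == 0L) stop("no points")
  sid <- as.integer(round((pts[, 1L] - min(pts[, 1L])) / dx))
  slices <- sort(unique(sid))
  if (length(slices) == 0L) stop("no slices")
  slice_x <- vapply(slices, function(s) mean(pts[sid == s, 1L]), 0)
  comp <- integer(nrow(pts))       # component id within slice
  ncomp <- integer(length(slices)) # components per slice
  # grid phase per axis (circular mean of the fractional voxel offsets):
  # robust to sub-voxel jitter, a no-op for off-grid clouds
  snap_axis <- function(v) {
    ang <- 2 * pi * ((v / dx) %% 1)
    ph <- Arg(mean(exp(1i * ang))) / (2 * pi)
    (round(v / dx - ph) + ph) * dx
  }
  ysnap <- snap_axis(pts[, 2L]); zsnap <- snap_axis(pts[, 3L])
  for (k in seq_along(slices)) {
    idx <- which(sid == slices[k])
    if (length(idx) == 1L) {
      comp[idx] <- 1L; ncomp[k] <- 1L; next
    }
    # cluster at the image's native resolution: snapping to the estimated
    # dx grid keeps sub-voxel segmentation jitter from fragmenting a contour
    yz <- cbind(ysnap[idx], zsnap[idx])
    hc <- stats::hclust(stats::dist(yz), method = "single")
    cl <- stats::cutree(hc, h = linking_factor * dx)
    # fold minor fragments (fewer than 3 points or <15% of the slice) into
    # the nearest substantial component
    repeat {
      sizes <- tabulate(cl)
      minor <- which(sizes < pmax(3, 0.15 * length(idx)))
      if (length(minor) == 0L || length(minor) == length(sizes)) break
      m <- minor[1L]
      dmat <- as.matrix(stats::dist(yz))
      rest <- which(cl != m)
      tgt <- cl[rest[which.min(apply(dmat[cl == m, rest, drop = FALSE],
                                     2L, min))]]
      cl[cl == m] <- tgt
      cl <- match(cl, sort(unique(cl)))
    }
    ncomp[k] <- max(cl)
    if (ncomp[k] > 2L)
      stop("unsupported topology: slice with more than 2 components")
    comp[idx] <- cl
  }
  branch <- rep(NA_integer_, nrow(pts))
  part <- rep("Part1", nrow(pts))
  tcx <- NA_real_
  if (any(ncomp == 2L)) {
    # the branched region is the terminal run of two-component slices
    # (either end); isolated flickers near the transition are folded back
    r <- rle(ncomp)
    nr <- length(r$lengths)
    two_first <- if (r$values[1L] == 2L && r$values[nr] == 2L)
      stop("unsupported topology: branches at both ends") else
        r$values[1L] == 2L
    run_idx <- if (two_first) seq_len(r$lengths[1L]) else
      (length(slices) - r$lengths[nr] + 1L):length(slices)
    if (r$values[if (two_first) 1L else nr] != 2L)
      stop("unsupported topology: component count pattern")
    flicker <- setdiff(which(ncomp == 2L), run_idx)
    if (length(flicker) > 0L) {
      warning("merging isolated two-component slices outside the branch run")
      for (k in flicker) {
        idx <- which(sid == slices[k])
        comp[idx] <- 1L
      }
      ncomp[flicker] <- 1L
    }
    two_idx <- which(ncomp == 2L)
    tcx <- if (two_first) slice_x[max(two_idx)] else slice_x[min(two_idx)]
    # walk outward from the topology change, matching components to the
    # previous slice's branch centroids
    ord <- if (two_first) rev(two_idx) else two_idx
    prev_cent <- NULL
    for (k in ord) {
      idx <- which(sid == slices[k])
      cent <- rbind(colMeans(pts[idx[comp[idx] == 1L], 2:3, drop = FALSE]),
                    colMeans(pts[idx[comp[idx] == 2L], 2:3, drop = FALSE]))
      if (is.null(prev_cent)) {
        # branch 1 = smaller mean y (tie: smaller mean z)
        b_of_comp <- order(cent[, 1L], cent[, 2L])
        lab <- integer(2L); lab[b_of_comp] <- 1:2
      } else {
        d_straight <- sum((cent - prev_cent)^2)
        d_swapped <- sum((cent[2:1, ] - prev_cent)^2)
        lab <- if (d_straight <= d_swapped) 1:2 else 2:1
      }
      branch[idx] <- lab[comp[idx]]
      prev_cent <- cent[order(lab), , drop = FALSE]
      part[idx] <- c("Part2", "Part3")[branch[idx]]
    }
    in_buffer <- abs(pts[, 1L] - tcx) <= part4_buffer_k * dx + 1e-9
    part[in_buffer] <- "Part4"
  }
  structure(list(part = factor(part,
                               levels = c("Part1", "Part2", "Part3", "Part4")),
                 topology_change_x = tcx,
                 slice_id = sid, slice_x = slice_x, slices = slices,
                 ncomp = ncomp, branch = branch),
            class = "partitioned_geometry")
}

#' Map points near a plane onto it
#'
#' Selects all points with `|x - plane_x| < dx/2` (half-open, so each point
#' belongs to exactly one plane on a regular slice grid) and projects them
#' orthogonally onto the y-z plane at `plane_x`.
#'
#' @param cloud a [raw_point_cloud()].
#' @param plane_x plane position (mm).
#' @param dx slab thickness (mm), usually the slice spacing.
#' @return matrix with columns y, z.
#' @export
build_section <- function(cloud, plane_x, dx = cloud$slice_spacing_dx) {
  if (dx <= 0) stop("dx must be > 0")
  sel <- abs(cloud$points[, 1L] - plane_x) < dx / 2
  if (!any(sel)) stop("no points within dx/2 of plane_x")
  cloud$points[sel, 2:3, drop = FALSE]
}

# perimeter of the angularly ordered polygon through 2-D points
contour_perimeter <- function(points2d) {
  p <- order_by_angle(points2d)
  q <- rbind(p, p[1L, ])
  sum(sqrt(rowSums(diff(q)^2)))
}

order_by_angle <- function(points2d) {
  p <- as.matrix(points2d)
  ctr <- colMeans(p)
  ang <- atan2(p[, 2L] - ctr[2L], p[, 1L] - ctr[1L])
  p[order(ang), , drop = FALSE]
}

#' Resample a cross-section contour at equal arc spacing
#'
#' Points are ordered by angle around their centroid (vessel lumens are
#' star-shaped, so this recovers the contour), closed into a polygonal
#' chain, and resampled by linear interpolation at `N = round(perimeter/dL)`
#' exactly equal arc steps of `perimeter/N`. A fixed `n_points` may be given
#' instead, which downstream generator-line correspondence requires.
#'
#' @param points2d matrix of contour points (two columns, mm).
#' @param dL target arc spacing (mm); 0.1 mm by default.
#' @param n_points override the computed point count.
#' @return ordered (counter-clockwise) closed contour, `N x 2`, stored
#'   without the duplicate end point.
#' @export
resample_contour <- function(points2d, dL = 0.1, n_points = NULL) {
  p <- as.matrix(points2d)
  if (nrow(p) < 3L) stop("need at least 3 contour points")
  scale <- max(apply(p, 2L, function(c) diff(range(c))))
  p <- order_by_angle(p)
  y <- p[, 1L]; z <- p[, 2L]
  y2 <- c(y[-1L], y[1L]); z2 <- c(z[-1L], z[1L])
  if (abs(sum(y * z2 - y2 * z)) < 1e-10 * max(scale, 1)^2)
    stop("degenerate (collinear) contour points")
  q <- rbind(p, p[1L, ])
  seg <- sqrt(rowSums(diff(q)^2))
  cl <- c(0, cumsum(seg))
  P <- cl[length(cl)]
  N <- if (is.null(n_points)) round(P / dL) else as.integer(n_points)
  if (N < 3L) stop("contour too short for the requested dL")
  s <- (seq_len(N) - 1L) * P / N
  iv <- findInterval(s, cl, rightmost.closed = TRUE)
  iv <- pmin(pmax(iv, 1L), nrow(q) - 1L)
  t <- (s - cl[iv]) / pmax(seg[iv], 1e-300)
  snap <- abs(s - cl[iv]) < 1e-12 * max(P, 1)
  t[snap] <- 0
  out <- q[iv, , drop = FALSE] * (1 - t) + q[iv + 1L, , drop = FALSE] * t
  # normalize the start to the angular minimum so resampling an
  # already-equispaced contour reproduces it exactly
  ctr <- colMeans(out)
  s0 <- which.min(atan2(out[, 2L] - ctr[2L], out[, 1L] - ctr[1L]))
  if (s0 > 1L) out <- out[c(s0:N, 1L:(s0 - 1L)), , drop = FALSE]
  colnames(out) <- colnames(p)
  out
}

#' Locate the bifurcation point
#'
#' Finds the pair of contour points, one on the first plane of each branch,
#' with the minimum Euclidean distance, then returns the Part4 point closest
#' to the segment joining that pair. Ties are broken by smallest x, then y,
#' then z.
#'
#' @param sec2,sec3 contour points (n x 3) of the first Part2 / Part3 planes.
#' @param part4_points Part4 points (n x 3).
#' @return list with `point` (the bifurcation point), `p2`, `p3` (the
#'   closest branch pair) and `distance` (point-to-segment distance, mm).
#' @export
find_bifurcation_point <- function(sec2, sec3, part4_points) {
  sec2 <- as.matrix(sec2); sec3 <- as.matrix(sec3)
  part4_points <- as.matrix(part4_points)
  if (nrow(sec2) == 0L || nrow(sec3) == 0L) stop("empty branch section")
  if (nrow(part4_points) == 0L) stop("empty Part4")
  d2 <- outer(seq_len(nrow(sec2)), seq_len(nrow(sec3)), function(a, b)
    rowSums((sec2[a, , drop = FALSE] - sec3[b, , drop = FALSE])^2))
  hit <- arrayInd(which.min(d2), dim(d2))
  p2 <- sec2[hit[1L], ]; p3 <- sec3[hit[2L], ]
  ds <- dist_point_segment(part4_points, p2, p3)
  best <- order(ds, part4_points[, 1L], part4_points[, 2L],
                part4_points[, 3L])[1L]
  list(point = part4_points[best, ], p2 = p2, p3 = p3,
       distance = ds[best])
}

#' Cross-section on the circle through three bifurcation reference points
#'
#' Constructs the unique circle passing through the bifurcation point and
#' one reference point from each branch, then collects the Part4 points
#' lying within `tol` of the circle's supporting plane and within `tol` of
#' the circle radially; these are projected onto the plane and resampled at
#' `dL`. This classifies the Part4 points that belong to the junction
#' section itself.
#'
#' @param bif_point the bifurcation point (length-3).
#' @param p2,p3 one reference point from Part2 and Part3 (length-3).
#' @param part4_points Part4 points (n x 3).
#' @param tol selection tolerance (mm).
#' @param dL resampling arc spacing (mm).
#' @return list of class `cross_section` with `circle` (center, radius,
#'   normal), `contour2d` (in-plane), `contour3d`, and `part = "Part4"`.
#' @export
inscribed_circle_section <- function(bif_point, p2, p3, part4_points,
                                     tol = 0.35, dL = 0.1) {
  p1 <- as.numeric(bif_point)
  e1 <- as.numeric(p2) - p1
  e2 <- as.numeric(p3) - p1
  n <- c(e1[2L] * e2[3L] - e1[3L] * e2[2L],
         e1[3L] * e2[1L] - e1[1L] * e2[3L],
         e1[1L] * e2[2L] - e1[2L] * e2[1L])
  nn <- sqrt(sum(n * n))
  scale <- max(sqrt(sum(e1^2)), sqrt(sum(e2^2)))
  if (nn < 1e-10 * max(scale, 1)^2)
    stop("collinear reference points: no unique circle")
  n <- n / nn
  g <- rbind(c(sum(e1 * e1), sum(e1 * e2)),
             c(sum(e1 * e2), sum(e2 * e2)))
  ab <- solve(g, 0.5 * c(sum(e1 * e1), sum(e2 * e2)))
  center <- p1 + ab[1L] * e1 + ab[2L] * e2
  radius <- sqrt(sum((p1 - center)^2))
  p4 <- as.matrix(part4_points)
  rel <- sweep(p4, 2L, center)
  dplane <- as.numeric(rel %*% n)
  proj <- p4 - tcrossprod(dplane, n)
  rad <- sqrt(rowSums(sweep(proj, 2L, center)^2))
  sel <- abs(dplane) < tol & abs(rad - radius) < tol
  if (sum(sel) < 3L)
    stop("fewer than 3 Part4 points lie on the inscribed circle")
  u <- e1 / sqrt(sum(e1 * e1))
  w <- c(n[2L] * u[3L] - n[3L] * u[2L],
         n[3L] * u[1L] - n[1L] * u[3L],
         n[1L] * u[2L] - n[2L] * u[1L])
  q <- sweep(proj[sel, , drop = FALSE], 2L, center)
  pts2 <- cbind(q %*% u, q %*% w)
  contour2d <- resample_contour(pts2, dL)
  contour3d <- sweep(contour2d[, 1L] %o% u + contour2d[, 2L] %o% w,
                     2L, center, "+")
  structure(list(circle = list(center = center, radius = radius, normal = n),
                 contour2d = contour2d, contour3d = contour3d,
                 part = "Part4", dL = dL),
            class = "cross_section")
}
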