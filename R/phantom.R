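#' Synthetic vessel phantom specification
#'
#' Describes an analytic vessel used to generate test geometries with known
#' ground truth: a straight tube, a curved (torus-segment) tube, or a
#' carotid-like bifurcating vessel (union of three capsule-swept cylinders
#' meeting at a point). Dimensions are chosen to emulate carotid arteries on
#' medical-checkup CT (parent diameter ~7 mm on a ~0.7 mm/px grid).
#'
#' @param kind `"straight"`, `"curved"` or `"bifurcating"`.
#' @param diameter parent lumen diameter (mm).
#' @param length total extent along the slice (x) axis (mm).
#' @param child_diameters two child diameters (mm), bifurcating only;
#'   defaults to 0.8 and 0.65 of the parent (ICA/ECA-like).
#' @param bifurcation_half_angle half-angle between the children (degrees).
#' @param parent_fraction fraction of `length` taken by the parent branch.
#' @param bend_angle total centerline bend (degrees), curved only.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("straight", "curved", "bifurcating"),
                         diameter = 7.1, length = 50,
                         child_diameters = diameter * c(0.8, 0.65),
                         bifurcation_half_angle = 25,
                         parent_fraction = 0.5,
                         bend_angle = 30) {
  kind <- match.arg(kind)
  if (diameter <= 0 || length <= 0) stop("diameter and length must be > 0")
  if (kind == "bifurcating") {
    if (length(child_diameters) != 2L || any(child_diameters <= 0))
      stop("child_diameters must be two positive values")
    if (bifurcation_half_angle <= 0 || bifurcation_half_angle >= 80)
      stop("bifurcation_half_angle must be in (0, 80) degrees")
    # children must stay separated once split: they do so for straight axes
    # fanning out from a single point, which is the only layout generated
  }
  if (kind == "curved" && (bend_angle <= 0 || bend_angle >= 90))
    stop("bend_angle must be in (0, 90) degrees")
  structure(list(kind = kind, diameter = diameter, length = length,
                 child_diameters = child_diameters,
                 bifurcation_half_angle = bifurcation_half_angle,
                 parent_fraction = parent_fraction,
                 bend_angle = bend_angle),
            class = "phantom_spec")
}

# axis segments and radii of the capsule primitives (bifurcating)
phantom_segments <- function(spec) {
  r <- spec$diameter / 2
  L <- spec$length
  if (spec$kind == "straight")
    return(list(a = matrix(c(0, 0, 0), 1), b = matrix(c(L, 0, 0), 1), r = r))
  if (spec$kind == "bifurcating") {
    th <- spec$bifurcation_half_angle * pi / 180
    xb <- spec$parent_fraction * L
    lc <- (L - xb) / cos(th)
    a <- rbind(c(0, 0, 0), c(xb, 0, 0), c(xb, 0, 0))
    b <- rbind(c(xb, 0, 0),
               c(xb, 0, 0) + lc * c(cos(th),  sin(th), 0),
               c(xb, 0, 0) + lc * c(cos(th), -sin(th), 0))
    return(list(a = a, b = b, r = c(r, spec$child_diameters / 2)))
  }
  stop("curved phantoms have no straight segments")
}

# distance from points (n x 3) to one 3-D segment a-b
dist_point_segment <- function(pts, a, b) {
  ab <- b - a
  len2 <- sum(ab * ab)
  d <- sweep(pts, 2L, a)
  t <- if (len2 > 0) pmin(pmax((d %*% ab) / len2, 0), 1) else rep(0, nrow(pts))
  proj <- d - tcrossprod(as.numeric(t), ab)
  sqrt(rowSums(proj * proj))
}

# approximate signed distance to the phantom surface; exact sign everywhere,
# magnitude exact away from junctions and flat-end edges
phantom_sdf <- function(spec, pts) {
  pts <- as.matrix(pts)
  r <- spec$diameter / 2
  L <- spec$length
  if (spec$kind %in% c("straight", "bifurcating")) {
    seg <- phantom_segments(spec)
    d <- Inf
    for (k in seq_along(seg$r))
      d <- pmin(d, dist_point_segment(pts, seg$a[k, ], seg$b[k, ]) - seg$r[k])
    return(pmax(d, -pts[, 1L], pts[, 1L] - L))
  }
  # curved: torus segment, centerline arc of radius Rc in the x-y plane
  bend <- spec$bend_angle * pi / 180
  rc <- L / bend
  px <- pts[, 1L]; py <- pts[, 2L]; pz <- pts[, 3L]
  rho <- sqrt(px^2 + (py - rc)^2)
  tor <- sqrt((rho - rc)^2 + pz^2) - r
  c1 <- rc * c(sin(bend), 1 - cos(bend), 0)
  t1 <- c(cos(bend), sin(bend), 0)
  pmax(tor, -px, (px - c1[1L]) * t1[1L] + (py - c1[2L]) * t1[2L])
}

phantom_inside <- function(spec, pts) phantom_sdf(spec, pts) < 0

#' Voxelize a phantom on a regular grid
#'
#' A voxel is occupied iff its center lies inside the analytic lumen,
#' emulating the discrete representation of a vessel on a medical image grid
#' (default resolution 0.7 mm/px).
#'
#' @param spec a [phantom_spec()].
#' @param voxel_size edge length in mm/px.
#' @param max_cells guard against accidental huge grids.
#' @return object of class `voxel_model`: `occupancy` (3-D logical array),
#'   `voxel_size`, `origin` (mm position of voxel center `[1,1,1]`).
#' @export
voxelize <- function(spec, voxel_size = 0.7, max_cells = 3e7) {
  if (voxel_size <= 0) stop("voxel_size must be > 0")
  half <- max(spec$diameter, max(if (spec$kind == "bifurcating")
    spec$child_diameters else 0)) / 2
  pad <- half + 2 * voxel_size
  ylim <- switch(spec$kind,
    straight = c(-pad, pad),
    curved = c(-pad, spec$length / (spec$bend_angle * pi / 180) *
                 (1 - cos(spec$bend_angle * pi / 180)) + pad),
    bifurcating = {
      th <- spec$bifurcation_half_angle * pi / 180
      w <- (spec$length * (1 - spec$parent_fraction)) * tan(th) + pad
      c(-w, w)
    })
  # pixel-center convention: centers at (k + 1/2) * voxel_size, as on an
  # image grid whose voxel boundaries tile the scene
  grid_axis <- function(lo, hi, h)
    seq((floor(lo / h) - 1) * h + h / 2, hi + h, by = h)
  xg <- grid_axis(0, spec$length, voxel_size)
  yg <- grid_axis(ylim[1L], ylim[2L], voxel_size)
  zg <- grid_axis(-pad, pad, voxel_size)
  ncell <- length(xg) * length(yg) * length(zg)
  if (ncell > max_cells) stop("voxel grid would exceed max_cells")
  pts <- cbind(rep(xg, times = length(yg) * length(zg)),
               rep(rep(yg, each = length(xg)), times = length(zg)),
               rep(zg, each = length(xg) * length(yg)))
  occ <- array(phantom_inside(spec, pts),
               dim = c(length(xg), length(yg), length(zg)))
  if (!any(occ)) stop("no occupied voxels")
  structure(list(occupancy = occ, voxel_size = voxel_size,
                 origin = c(xg[1L], yg[1L], zg[1L])),
            class = "voxel_model")
}

#' Extract noisy surface points from a voxel model
#'
#' Returns the centers of occupied voxels that have at least one unoccupied
#' 6-neighbor (the voxel-model surface), optionally displaced radially within
#' their y-z slice, away from the slice centroid, by
#' Uniform(-jitter_amplitude, +jitter_amplitude). The jitter stands in for
#' the partial-volume / threshold noise of real segmentations, which pushes
#' the apparent surface roughness to roughly 10% of the vessel diameter at
#' 0.7 mm/px.
#'
#' The first and last occupied slices are the vessel's flat cut ends, not
#' lumen wall; they are dropped by default (`trim_ends = TRUE`).
#'
#' @param vm a [voxelize()] result.
#' @param jitter_amplitude max radial displacement (mm).
#' @param seed RNG seed; the same seed always yields the same cloud.
#' @param trim_ends drop the first and last occupied slices (cut faces).
#' @return a [raw_point_cloud()] with `slice_spacing_dx = voxel_size`.
#' @export
extract_surface_points <- function(vm, jitter_amplitude = 0, seed = 1L,
                                   trim_ends = TRUE) {
  occ <- vm$occupancy
  d <- dim(occ)
  pad_shift <- function(along, by) {
    out <- array(TRUE, d)   # outside the grid counts as empty
    src <- lapply(d, seq_len)
    dst <- lapply(d, seq_len)
    rng <- seq_len(d[along] - abs(by))
    if (by > 0) {
      src[[along]] <- rng + by; dst[[along]] <- rng
    } else {
      src[[along]] <- rng; dst[[along]] <- rng + abs(by)
    }
    out[dst[[1L]], dst[[2L]], dst[[3L]]] <- !occ[src[[1L]], src[[2L]], src[[3L]]]
    out
  }
  nb_empty <- array(FALSE, d)
  for (al in 1:3) for (by in c(-1L, 1L))
    nb_empty <- nb_empty | pad_shift(al, by)
  boundary <- occ & nb_empty
  idx <- which(boundary, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("voxel model has no boundary voxels")
  if (trim_ends) {
    occ_ix <- range(which(apply(occ, 1L, any)))
    keep <- idx[, 1L] != occ_ix[1L] & idx[, 1L] != occ_ix[2L]
    if (!any(keep)) stop("voxel model has no boundary voxels between its ends")
    idx <- idx[keep, , drop = FALSE]
  }
  pts <- sweep((idx - 1) * vm$voxel_size, 2L, vm$origin, "+")
  colnames(pts) <- c("x", "y", "z")
  if (jitter_amplitude > 0) {
    ord <- order(pts[, 1L], pts[, 2L], pts[, 3L])
    pts <- pts[ord, , drop = FALSE]
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv))
    set.seed(seed)
    u <- stats::runif(nrow(pts), -jitter_amplitude, jitter_amplitude)
    sl <- match(pts[, 1L], unique(pts[, 1L]))
    cy <- ave(pts[, 2L], sl)
    cz <- ave(pts[, 3L], sl)
    dy <- pts[, 2L] - cy; dz <- pts[, 3L] - cz
    nrm <- sqrt(dy^2 + dz^2)
    ok <- nrm > 1e-12
    pts[ok, 2L] <- pts[ok, 2L] + u[ok] * dy[ok] / nrm[ok]
    pts[ok, 3L] <- pts[ok, 3L] + u[ok] * dz[ok] / nrm[ok]
  }
  raw_point_cloud(pts, slice_spacing_dx = vm$voxel_size,
                  meta = sprintf("phantom surface, jitter %.3g mm, seed %d",
                                 jitter_amplitude, as.integer(seed)))
}

#' Analytic ground-truth surface of a phantom
#'
#' Finely triangulated true surface plus its volume: closed form for the
#' straight tube (\eqn{\pi r^2 L}) and the torus-segment bend
#' (\eqn{\pi r^2 R_c \phi}, Pappus), numerically from the watertight truth
#' mesh for the bifurcating union.
#'
#' @param spec a [phantom_spec()].
#' @param n_around contour points around the lumen.
#' @param axial_step spacing of sections along the vessel (mm).
#' @return list with `mesh` (closed [surface_mesh()]) and `volume` (mm^3).
#' @export
analytic_truth <- function(spec, n_around = 96L, axial_step = 0.5) {
  r <- spec$diameter / 2
  L <- spec$length
  if (spec$kind == "straight") {
    xs <- seq(0, L, by = axial_step)
    if (xs[length(xs)] < L) xs <- c(xs, L)
    th <- 2 * pi * (seq_len(n_around) - 1) / n_around
    rings <- lapply(xs, function(x) cbind(x, r * cos(th), r * sin(th)))
    mesh <- ring_tube_mesh(rings)
    return(list(mesh = mesh, volume = pi * r^2 * L))
  }
  if (spec$kind == "curved") {
    bend <- spec$bend_angle * pi / 180
    rc <- L / bend
    phis <- seq(0, bend, length.out = max(8L, ceiling(L / axial_step) + 1L))
    th <- 2 * pi * (seq_len(n_around) - 1) / n_around
    rings <- lapply(phis, function(phi) {
      ctr <- rc * c(sin(phi), 1 - cos(phi), 0)
      er <- c(sin(phi), -cos(phi), 0)   # radially outward from arc center
      ez <- c(0, 0, 1)
      cbind(ctr[1L] + r * (cos(th) * er[1L]),
            ctr[2L] + r * (cos(th) * er[2L]),
            ctr[3L] + r * sin(th))
    })
    mesh <- ring_tube_mesh(rings)
    return(list(mesh = mesh, volume = pi * r^2 * rc * bend))
  }
  # bifurcating: exact planar contours by radial bisection on the analytic
  # inside test, lofted with the same watertight pants stitch the pipeline uses
  sec <- truth_sections_bifurcating(spec, n_around, axial_step)
  mesh <- pants_mesh(sec$parent, sec$child2, sec$child3)
  list(mesh = mesh, volume = mesh_volume(mesh))
}

# planar contours of the bifurcating union at x = const planes
truth_sections_bifurcating <- function(spec, n_around, axial_step) {
  seg <- phantom_segments(spec)
  L <- spec$length
  th <- spec$bifurcation_half_angle * pi / 180
  xb <- spec$parent_fraction * L
  xs <- seq(0, L, by = axial_step)
  if (xs[length(xs)] < L) xs <- c(xs, L)
  rmax <- max(seg$r) * 3 + L * tan(th)
  inside_set <- function(pts, active) {
    d <- Inf
    for (k in active)
      d <- pmin(d, dist_point_segment(pts, seg$a[k, ], seg$b[k, ]) - seg$r[k])
    d < 0 & pts[, 1L] >= 0 & pts[, 1L] <= L
  }
  # radial bisection from a seed against the primitives forming one
  # component only, so rays never lock onto the other branch's wall
  contour_at <- function(x, seed_yz, n_pts, active = seq_along(seg$r)) {
    ang <- 2 * pi * (seq_len(n_pts) - 1) / n_pts
    ca <- cos(ang); sa <- sin(ang)
    lo <- rep(0, n_pts); hi <- rep(rmax, n_pts)
    for (it in 1:48) {
      mid <- (lo + hi) / 2
      p <- cbind(x, seed_yz[1L] + mid * ca, seed_yz[2L] + mid * sa)
      ins <- inside_set(p, active)
      lo[ins] <- mid[ins]; hi[!ins] <- mid[!ins]
    }
    mid <- (lo + hi) / 2
    cbind(x, seed_yz[1L] + mid * ca, seed_yz[2L] + mid * sa)
  }
  # slice connectivity decided on the y axis (z = 0, where all primitives
  # are widest): one contour while {y : (x, y, 0) inside} is a single run
  parent <- list(); child2 <- list(); child3 <- list()
  for (x in xs) {
    dy <- max(0, x - xb) * tan(th)
    yy <- seq(-(dy + rmax), dy + rmax, length.out = 801L)
    ins <- phantom_inside(spec, cbind(x, yy, 0))
    rl <- rle(ins)
    runs <- sum(rl$values)
    if (runs == 0L) next
    if (runs > 2L) stop("unexpected slice topology in truth sections")
    if (runs == 1L) {
      iy <- which(ins)
      seed_y <- yy[iy[ceiling(length(iy) / 2)]]
      parent[[length(parent) + 1L]] <- contour_at(x, c(seed_y, 0), n_around)
    } else if ({
      ends <- cumsum(rl$lengths)
      tr <- which(rl$values)              # indices of the two inside runs
      gap <- yy[ends[tr[2L] - 1L] + 1L] - yy[ends[tr[1L]]]
      gap < 0.25
    }) {
      # children barely separated: skip the plane, the junction stitch
      # spans it
      next
    } else {
      nc <- max(24L, ceiling(n_around * 0.7))
      act_of <- function(seed_yz) {
        p <- cbind(x, seed_yz[1L], seed_yz[2L])
        which(vapply(seq_along(seg$r), function(k)
          dist_point_segment(p, seg$a[k, ], seg$b[k, ]) < seg$r[k], TRUE))
      }
      child2[[length(child2) + 1L]] <-
        contour_at(x, c(dy, 0), nc, act_of(c(dy, 0)))
      child3[[length(child3) + 1L]] <-
        contour_at(x, c(-dy, 0), nc, act_of(c(-dy, 0)))
    }
  }
  if (length(child2) < 2L)
    stop("phantom too short for its bifurcation: no separated child slices")
  list(parent = parent, child2 = child2, child3 = child3)
}

#' Mean absolute distance from points to the true phantom surface
#'
#' @param pts n x 3 matrix of points (mm).
#' @param spec the generating [phantom_spec()].
#' @return mean of |signed distance| over the points (mm).
#' @export
phantom_surface_distance <- function(pts, spec) {
  mean(abs(phantom_sdf(spec, pts)))
}
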