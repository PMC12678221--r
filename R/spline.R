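# Natural cubic splines for generator curves, solved for all generator
# lines at once (one tridiagonal system with a matrix right-hand side).

# Thomas solve of the natural-spline system for second derivatives M;
# Y is n x m (one column per series). Returns n x m matrix of M values
# with M[1,] = M[n,] = 0.
natural_spline_m <- function(x, Y) {
  n <- length(x)
  h <- diff(x)
  if (any(h <= 0)) stop("knots must be strictly increasing")
  M <- matrix(0, n, ncol(Y))
  if (n < 3L) return(M)
  dY <- diff(Y) / h                       # (n-1) x m slopes
  rhs <- 6 * (dY[-1L, , drop = FALSE] - dY[-(n - 1L), , drop = FALSE])
  diag_main <- 2 * (h[-(n - 1L)] + h[-1L])  # length n-2
  sub <- if (n > 3L) h[2:(n - 2L)] else numeric(0)  # off-diagonals, n-3 of them
  m <- n - 2L
  cp <- numeric(m); rhs2 <- rhs
  cp[1L] <- if (m > 1L) sub[1L] / diag_main[1L] else 0
  rhs2[1L, ] <- rhs[1L, ] / diag_main[1L]
  if (m > 1L) {
    for (i in 2:m) {
      denom <- diag_main[i] - sub[i - 1L] * cp[i - 1L]
      if (i < m) cp[i] <- sub[i] / denom
      rhs2[i, ] <- (rhs[i, ] - sub[i - 1L] * rhs2[i - 1L, ]) / denom
    }
    for (i in (m - 1L):1L)
      rhs2[i, ] <- rhs2[i, ] - cp[i] * rhs2[i + 1L, ]
  }
  M[2:(n - 1L), ] <- rhs2
  M
}

# piecewise coefficients per interval [x_i, x_{i+1}]:
# S_i(x) = a (x-x_i)^3 + b (x-x_i)^2 + c (x-x_i) + d
natural_spline_coef <- function(x, Y) {
  n <- length(x)
  h <- diff(x)
  M <- natural_spline_m(x, Y)
  lo <- seq_len(n - 1L)
  Ylo <- Y[lo, , drop = FALSE]; Yhi <- Y[lo + 1L, , drop = FALSE]
  Mlo <- M[lo, , drop = FALSE]; Mhi <- M[lo + 1L, , drop = FALSE]
  list(a = (Mhi - Mlo) / (6 * h),
       b = Mlo / 2,
       c = (Yhi - Ylo) / h - h * (2 * Mlo + Mhi) / 6,
       d = Ylo)
}

#' Fit per-generator natural cubic splines through aligned sections
#'
#' For each generator line (fixed contour index) the y and z coordinates are
#' interpolated along x with natural cubic splines (zero second derivative
#' at the two ends), giving C2-continuous longitudinal curves through the
#' section reference points. With fewer than 3 sections the fit degrades to
#' linear interpolation and the result is flagged.
#'
#' @param sections list of aligned cross-sections: each element a list with
#'   `x` (plane position) and `pts` (N x 2 contour, same N and aligned
#'   indices throughout).
#' @return object of class `generator_spline_set`: `knots`, coefficient
#'   lists `coef_y`, `coef_z` (each with `(n-1) x N` matrices `a`, `b`, `c`,
#'   `d`), point count `N`, and `linear_fallback` flag.
#' @export
fit_slice_splines <- function(sections) {
  if (length(sections) < 2L) stop("need at least 2 sections")
  N <- nrow(sections[[1L]]$pts)
  if (any(vapply(sections, function(s) nrow(s$pts), 1L) != N))
    stop("sections have mismatched point counts")
  x <- vapply(sections, function(s) s$x, 0)
  o <- order(x)
  x <- x[o]; sections <- sections[o]
  Yy <- do.call(rbind, lapply(sections, function(s) s$pts[, 1L]))
  Yz <- do.call(rbind, lapply(sections, function(s) s$pts[, 2L]))
  linear <- length(sections) < 3L
  if (linear) warning("fewer than 3 sections: linear interpolation fallback")
  structure(list(knots = x,
                 coef_y = natural_spline_coef(x, Yy),
                 coef_z = natural_spline_coef(x, Yz),
                 N = N, linear_fallback = linear),
            class = "generator_spline_set")
}

eval_coef <- function(knots, coef, xd) {
  iv <- findInterval(xd, knots, rightmost.closed = TRUE)
  iv <- pmin(pmax(iv, 1L), length(knots) - 1L)
  t <- xd - knots[iv]
  ((coef$a[iv, , drop = FALSE] * t + coef$b[iv, , drop = FALSE]) * t +
     coef$c[iv, , drop = FALSE]) * t + coef$d[iv, , drop = FALSE]
}

#' Evaluate generator splines on a dense x grid
#'
#' Samples every generator line at `x = x_min, x_min + step, ...` up to and
#' including `x_max` (the paper-style dense resampling at 0.1 mm).
#'
#' @param gss a [fit_slice_splines()] result.
#' @param step sampling step (mm).
#' @return list with `x` (dense grid), `Y`, `Z` (length(x) x N matrices).
#' @export
evaluate_splines <- function(gss, step = 0.1) {
  if (step <= 0) stop("step must be > 0")
  x0 <- gss$knots[1L]; x1 <- gss$knots[length(gss$knots)]
  if (step > x1 - x0) stop("step larger than the knot span")
  k <- floor((x1 - x0) / step + 1e-9)
  xd <- x0 + step * (0:k)
  if (x1 - xd[length(xd)] > 1e-9 * max(1, abs(x1))) xd <- c(xd, x1)
  list(x = xd,
       Y = eval_coef(gss$knots, gss$coef_y, xd),
       Z = eval_coef(gss$knots, gss$coef_z, xd))
}

#' Selective standard-deviation / median noise filter
#'
#' For each sample with a full window of `m` samples before and after
#' (center included), the mean, population standard deviation and median of
#' the window are computed from the unfiltered series; samples falling
#' outside the open interval (mean - q*sigma, mean + q*sigma) are replaced
#' by the window median. The `m` samples at each end are never edited: a
#' truncated end window flags any locally monotone series end as an
#' outlier (for three samples on a ramp, |v - mean| always exceeds the
#' window sigma), which would systematically clip the vessel ends. Most
#' samples are left untouched, which is what keeps the volume change of
#' the smoothed geometry small. Repeating the pass removes progressively
#' more low-frequency noise; a single pass is the default operating point.
#'
#' @param values numeric series (a generator-curve coordinate).
#' @param q judgment-range multiplier (dimensionless).
#' @param m window half-width in samples.
#' @param passes number of filter passes.
#' @return filtered series, same length.
#' @export
noise_filter_series <- function(values, q = 1, m = 2, passes = 1) {
  v <- as.numeric(values)
  n <- length(v)
  if (q <= 0 || m < 1 || passes < 1) stop("invalid filter parameters")
  if (n < 2 * m + 1) stop("series shorter than the filter window")
  k <- 2L * m + 1L
  for (p in seq_len(passes)) {
    lo <- pmax(seq_len(n) - m, 1L)
    hi <- pmin(seq_len(n) + m, n)
    cnt <- hi - lo + 1L
    S1 <- c(0, cumsum(v)); S2 <- c(0, cumsum(v^2))
    mu <- (S1[hi + 1L] - S1[lo]) / cnt
    sig <- sqrt(pmax(0, (S2[hi + 1L] - S2[lo]) / cnt - mu^2))
    med <- stats::runmed(v, k, endrule = "keep")
    replace <- cnt == k & !(mu - q * sig < v & v < mu + q * sig)
    v[replace] <- med[replace]
  }
  v
}
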