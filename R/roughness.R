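#' Sectioned arithmetic-mean roughness of a profile
#'
#' The profile is cut into sections of width `dX` along X. In each section a
#' least-squares reference line is fitted, the coordinates are rotated so
#' the line is horizontal, and the arithmetic-mean roughness
#' \eqn{Ra_i = (1/L) \int |h(X)| dX} is computed from the rotated residual
#' curve by the trapezoid rule, with L the rotated section length. The
#' averaged roughness is the plain mean of the per-section values.
#'
#' @param X,h profile samples: positions along the trace and heights (mm).
#' @param dX section width (mm), 5 by default.
#' @return object of class `roughness_report`: data frame `sections`
#'   (`lo`, `hi`, `L`, `Ra`), `Ra_bar`, `n_sections`, `dX`.
#' @export
section_roughness <- function(X, h, dX = 5) {
  o <- order(X)
  X <- as.numeric(X)[o]; h <- as.numeric(h)[o]
  span <- X[length(X)] - X[1L]
  if (span < dX) stop("profile spans less than one section of width dX")
  edges <- seq(X[1L], X[length(X)], by = dX)
  if (edges[length(edges)] < X[length(X)]) edges <- c(edges, edges[length(edges)] + dX)
  bin <- findInterval(X, edges, rightmost.closed = TRUE)
  rows <- list()
  for (b in sort(unique(bin))) {
    sel <- bin == b
    if (sum(sel) < 3L) {
      warning("section with fewer than 3 samples skipped")
      next
    }
    xs <- X[sel]; hs <- h[sel]
    mx <- mean(xs); mh <- mean(hs)
    sxx <- sum((xs - mx)^2)
    if (sxx == 0) {
      warning("degenerate (vertical) section skipped")
      next
    }
    slope <- sum((xs - mx) * (hs - mh)) / sxx
    th <- atan(slope)
    ct <- cos(th); st <- sin(th)
    xr <- ct * (xs - mx) + st * (hs - mh)
    hr <- -st * (xs - mx) + ct * (hs - mh)
    o2 <- order(xr)
    xr <- xr[o2]; hr <- abs(hr[o2])
    L <- xr[length(xr)] - xr[1L]
    if (L <= 0) next
    ra <- sum(diff(xr) * (hr[-1L] + hr[-length(hr)]) / 2) / L
    rows[[length(rows) + 1L]] <-
      data.frame(lo = edges[b], hi = edges[b + 1L], L = L, Ra = ra)
  }
  if (length(rows) == 0L) stop("no usable sections")
  sections <- do.call(rbind, rows)
  structure(list(sections = sections, Ra_bar = mean(sections$Ra),
                 n_sections = nrow(sections), dX = dX),
            class = "roughness_report")
}

#' @export
print.roughness_report <- function(x, ...) {
  cat(sprintf("roughness_report: %d sections (dX = %g mm), Ra_bar = %.4g mm\n",
              x$n_sections, x$dX, x$Ra_bar))
  invisible(x)
}

#' Averaged arithmetic-mean roughness of a vessel geometry
#'
#' Applies [section_roughness()] to the y(x) and z(x) profiles of every
#' generator curve and pools the per-section Ra values over all curves and
#' both coordinates; the reported value is their mean. Accepts the
#' generator-curve sets produced by [smooth_vessel()] (`curves` or
#' `curves_raw` entries, or curves rebuilt from a displaced mesh).
#'
#' @param curves list of per-part curve sets: each with `x` (vector) or `X`
#'   (per-vertex matrix) plus `Y` and `Z` matrices (sections x generators).
#' @param dX section width (mm).
#' @return object of class `roughness_report` with pooled `Ra_values`.
#' @export
geometry_roughness <- function(curves, dX = 5) {
  if (!is.null(curves$Y)) curves <- list(curves)
  ra <- c()
  for (cv in curves) {
    for (g in seq_len(ncol(cv$Y))) {
      xg <- if (!is.null(cv$X)) cv$X[, g] else cv$x
      for (hh in list(cv$Y[, g], cv$Z[, g])) {
        rep_g <- tryCatch(
          suppressWarnings(section_roughness(xg, hh, dX)),
          error = function(e) NULL)
        if (!is.null(rep_g)) ra <- c(ra, rep_g$sections$Ra)
      }
    }
  }
  if (length(ra) == 0L) stop("no usable traces")
  structure(list(sections = NULL, Ra_bar = mean(ra), Ra_values = ra,
                 n_sections = length(ra), dX = dX),
            class = "roughness_report")
}
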