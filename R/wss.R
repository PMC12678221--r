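#' Blood fluid properties
#'
#' Newtonian blood model used throughout the WSS utilities.
#'
#' @param mu dynamic viscosity (Pa s).
#' @param rho density (kg/m^3).
#' @return list with `mu`, `rho`.
#' @export
fluid_props <- function(mu = 0.004, rho = 1050) {
  if (mu <= 0 || rho <= 0) stop("mu and rho must be > 0")
  list(mu = mu, rho = rho)
}

#' Near-wall wall shear stress
#'
#' First-order WSS estimate from the velocity at the cell center nearest
#' the wall: \eqn{\tau = \mu u_p / y_p}.
#'
#' @param u_p near-wall velocity magnitude (m/s).
#' @param y_p wall distance of the cell center (m), > 0.
#' @param fluid a [fluid_props()] list.
#' @return shear stress (Pa), vectorized over `u_p` / `y_p`.
#' @export
wall_shear_from_near_wall <- function(u_p, y_p, fluid = fluid_props()) {
  if (any(y_p <= 0)) stop("y_p must be > 0")
  fluid$mu * u_p / y_p
}

#' Surface-averaged wall shear stress
#'
#' Area-weighted mean of the shear magnitude over the wall:
#' \eqn{\overline{WSS} = (1/S) \sum_f |\tau_f| A_f} with \eqn{S = \sum A_f}.
#'
#' @param field a [wall_field()].
#' @return surface-averaged WSS (Pa).
#' @export
surface_averaged_wss <- function(field) {
  mag <- if (!is.null(field$tau_vec)) sqrt(rowSums(field$tau_vec^2))
         else abs(field$tau_x)
  S <- sum(field$facet_area)
  if (S <= 0) stop("zero total area")
  sum(mag * field$facet_area) / S
}

#' Time-averaged surface-averaged WSS
#'
#' \eqn{TAWSS = (1/T)\int_T \overline{WSS}\, dt} by the trapezoid rule over
#' one period of samples.
#'
#' @param times sample times (s), strictly increasing.
#' @param wss surface-averaged WSS at each time (Pa).
#' @return TAWSS (Pa).
#' @export
tawss <- function(times, wss) {
  if (length(times) != length(wss)) stop("times and wss lengths differ")
  if (length(times) == 1L) {
    warning("single sample: TAWSS equals that sample")
    return(wss)
  }
  if (any(diff(times) <= 0)) stop("time stamps must be strictly increasing")
  T <- times[length(times)] - times[1L]
  sum(diff(times) * (wss[-1L] + wss[-length(wss)]) / 2) / T
}

#' Area-weighted distribution of the flow-direction shear component
#'
#' Fraction of wall surface area whose signed flow-direction shear
#' component tau_x (positive opposite to the flow) falls in each bin.
#' Values outside the given edges are collected in overflow bins.
#'
#' @param field a [wall_field()] with `tau_x`.
#' @param bin_edges increasing bin edges (Pa).
#' @return data frame with `lo`, `hi`, `fraction`; fractions sum to 1.
#' @export
wss_pdf <- function(field, bin_edges) {
  if (is.null(field$tau_x)) stop("field has no tau_x component")
  if (any(diff(bin_edges) <= 0)) stop("bin_edges must be increasing")
  tx <- field$tau_x
  lo <- c(if (any(tx < bin_edges[1L])) -Inf, bin_edges)
  hi <- c(bin_edges, if (any(tx >= bin_edges[length(bin_edges)])) Inf)
  edges <- unique(c(lo[1L], bin_edges, hi[length(hi)]))
  b <- findInterval(tx, edges, rightmost.closed = TRUE)
  S <- sum(field$facet_area)
  frac <- vapply(seq_len(length(edges) - 1L), function(k)
    sum(field$facet_area[b == k]) / S, 0)
  data.frame(lo = edges[-length(edges)], hi = edges[-1L], fraction = frac)
}

# Fourier coefficients of the common-carotid velocity waveform and the
# per-inlet area/amplitude constants
waveform_table <- list(
  LCA = list(A_art = 4.52e-5, beta = 3.85e-5),
  RCA = list(A_art = 4.80e-5, beta = 3.85e-5),
  LVA = list(A_art = 1.79e-5, beta = 3.77e-5),
  RVA = list(A_art = 1.51e-5, beta = 3.77e-5))
waveform_fourier <- list(a0 = 0.26,
                         a = c(-0.10, -0.10, -0.03, -0.014),
                         b = c(0.169, -0.002, -0.002, -0.002))

#' Pulsatile inlet waveform model
#'
#' Fourier model of the carotid/vertebral inlet velocity waveform:
#' the bracket term \eqn{a_0 + \sum_{i=1}^4 a_i\cos(2\pi i t/T) +
#' b_i\sin(2\pi i t/T)} scaled by the inlet cross-section area `A_art` and
#' the amplitude coefficient `beta`. The period is not fixed by the model
#' and defaults to 1 s.
#'
#' @param artery one of `"LCA"`, `"RCA"`, `"LVA"`, `"RVA"`.
#' @param T period (s).
#' @return object of class `waveform_model` with `A_art` (m^2), `beta`,
#'   Fourier coefficients `a0`, `a`, `b`, period `T` and lumen radius
#'   `R = sqrt(A_art/pi)` (m).
#' @export
waveform_model <- function(artery = c("LCA", "RCA", "LVA", "RVA"), T = 1.0) {
  artery <- match.arg(artery)
  if (T <= 0) stop("period T must be > 0")
  w <- waveform_table[[artery]]
  structure(c(w, waveform_fourier,
              list(T = T, R = sqrt(w$A_art / pi), artery = artery)),
            class = "waveform_model")
}

#' Evaluate the inlet waveform
#'
#' @param model a [waveform_model()].
#' @param t time (s), vectorized.
#' @return list with `bracket` (the Fourier sum, m/s) and `Q_art`
#'   (`A_art * beta * bracket`, the model's flow expression).
#' @export
waveform_flow <- function(model, t) {
  w <- 2 * pi * outer(t, 1:4) / model$T
  bracket <- model$a0 + cos(w) %*% model$a + sin(w) %*% model$b
  bracket <- as.numeric(bracket)
  list(bracket = bracket, Q_art = model$A_art * model$beta * bracket)
}

#' Parabolic inlet velocity profile
#'
#' Hagen-Poiseuille-shaped velocity distribution across the inlet disk:
#' \eqn{u(r,t) = (Q_{art}(t)/A_{art})(1 - (r/R)^2)}.
#'
#' @param model a [waveform_model()].
#' @param r radial position (m), 0 <= r <= R.
#' @param t time (s).
#' @return velocity (m/s), vectorized over `r`.
#' @export
inlet_velocity_profile <- function(model, r, t) {
  if (any(r < 0 | r > model$R)) stop("r must lie in [0, R]")
  q <- waveform_flow(model, t)
  (q$Q_art / model$A_art) * (1 - (r / model$R)^2)
}
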