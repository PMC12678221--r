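#' One Laplacian smoothing step
#'
#' Moves every vertex simultaneously by
#' \eqn{P_i \leftarrow P_i + s \sum_{j \in N(i)} w_{ij} (P_j - P_i)} with
#' uniform weights \eqn{w_{ij} = 1/|N(i)|}, the classic umbrella operator
#' used by Taubin-style mesh smoothing.
#'
#' @param mesh a `surface_mesh`.
#' @param scale step scale s (positive shrinks, negative inflates).
#' @return the displaced mesh (connectivity unchanged).
#' @export
laplacian_step <- function(mesh, scale) {
  adj <- mesh_adjacency(mesh)
  mesh$vertices <- laplacian_move(mesh$vertices, adj, scale)
  mesh
}

# unique undirected edges -> directed both ways, plus vertex degrees
mesh_adjacency <- function(mesh) {
  f <- mesh$faces
  nv <- nrow(mesh$vertices)
  i <- c(f[, 1L], f[, 2L], f[, 3L])
  j <- c(f[, 2L], f[, 3L], f[, 1L])
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(as.numeric(lo) * (nv + 1) + as.numeric(hi))
  lo <- lo[keep]; hi <- hi[keep]
  from <- c(lo, hi); to <- c(hi, lo)
  deg <- tabulate(from, nbins = nv)
  if (any(deg == 0L)) stop("mesh has isolated vertices")
  list(from = from, to = to, deg = deg, nv = nv)
}

laplacian_move <- function(V, adj, scale) {
  if (scale == 0) return(V)
  nb_sum <- rowsum(V[adj$to, , drop = FALSE], adj$from, reorder = TRUE)
  V + scale * (nb_sum / adj$deg - V)
}

#' Taubin lambda/mu mesh smoothing
#'
#' Alternates a shrinking Laplacian step (`lambda`) and an inflating step
#' (`mu < 0`) for `iterations` rounds; with `mu = 0` this degenerates to
#' plain (shrinking) Laplacian smoothing, the behaviour the pass-band
#' parameter is designed to correct. `mu` may be given directly or derived
#' from the pass-band `k_pb = 1/lambda + 1/mu`.
#'
#' @param mesh a closed `surface_mesh`.
#' @param lambda positive shrink factor, 0 < lambda < 1.
#' @param mu negative inflate factor; ignored when `passband` is given.
#' @param passband pass-band frequency k_pb; when supplied,
#'   `mu = 1/(k_pb - 1/lambda)`.
#' @param iterations number of lambda/mu rounds.
#' @return the smoothed mesh.
#' @export
taubin_smooth <- function(mesh, lambda = 0.5, mu = NULL, passband = NULL,
                          iterations = 10L) {
  if (lambda <= 0 || lambda >= 1) stop("lambda must be in (0, 1)")
  if (iterations < 1L) stop("iterations must be >= 1")
  if (!is.null(passband)) mu <- 1 / (passband - 1 / lambda)
  if (is.null(mu)) mu <- 0
  if (mu > 0) stop("mu must be <= 0")
  adj <- mesh_adjacency(mesh)
  V <- mesh$vertices
  for (it in seq_len(iterations)) {
    V <- laplacian_move(V, adj, lambda)
    if (mu != 0) V <- laplacian_move(V, adj, mu)
    if (!all(is.finite(V))) stop("Taubin smoothing diverged")
  }
  mesh$vertices <- V
  mesh
}
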