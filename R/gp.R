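#' Pairwise Euclidean distance matrix between sites
#'
#' @param sites Data frame with planar `x`, `y` (km), or a two-column matrix.
#' @return A symmetric n x n matrix of distances in km with zero diagonal.
#' @export
distance_matrix <- function(sites) {
  xy <- if (is.data.frame(sites)) cbind(sites$x, sites$y) else as.matrix(sites)
  as.matrix(stats::dist(xy))
}

#' Exponential spatial correlation
#'
#' `exp(-phi * d)`: correlation 1 at distance zero, decaying at rate `phi`
#' per km.
#'
#' @param d Distance(s), km, nonnegative.
#' @param phi Decay rate per km, positive.
#' @return Correlation value(s) in (0, 1].
#' @examples
#' spatial_correlation(29.957, phi = 0.1) # ~0.05
#' @export
spatial_correlation <- function(d, phi) {
  check_number(phi, "phi", lower = 0, strict_lower = TRUE)
  if (any(d < 0)) abort("Distances must be nonnegative.")
  exp(-phi * d)
}

#' Effective spatial range of an exponential correlation
#'
#' The distance at which spatial correlation between two locations drops to
#' `cutoff` (default 0.05): `-log(cutoff) / phi`, approximately `3 / phi`.
#'
#' @param phi Decay rate per km, positive.
#' @param cutoff Correlation level defining the range. Default 0.05.
#' @return Distance in km.
#' @seealso [decay_for_range()] for the inverse.
#' @examples
#' effective_range(0.15) # ~19.97 km
#' @export
effective_range <- function(phi, cutoff = 0.05) {
  if (any(phi <= 0)) abort("`phi` must be positive (non-decaying correlation).")
  check_number(cutoff, "cutoff", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  -log(cutoff) / phi
}

#' Decay rate giving a target effective spatial range
#'
#' @param range_km Effective range in km, positive.
#' @inheritParams effective_range
#' @return Decay rate `phi` per km.
#' @export
decay_for_range <- function(range_km, cutoff = 0.05) {
  if (any(range_km <= 0)) abort("`range_km` must be positive.")
  -log(cutoff) / range_km
}

#' Linear-model-of-coregionalization parameters
#'
#' The multivariate Gaussian process over `q` coefficient fields is built as
#' `w(s) = A v(s)`, where the `v_j` are independent unit-variance GPs with
#' exponential correlation at decay rate `phis[j]` and `A` is lower
#' triangular with positive diagonal. The implied cross-covariance between
#' coefficients at distance zero is `K = A A'`.
#'
#' @param A Lower-triangular q x q matrix with positive diagonal.
#' @param phis Vector of q positive decay rates (per km), one per latent
#'   process.
#' @return A list of class `"lmc_params"` with elements `A`, `phis`, `q`.
#' @export
lmc_params <- function(A, phis) {
  A <- as.matrix(A)
  q <- nrow(A)
  if (ncol(A) != q || length(phis) != q) {
    abort("`A` must be q x q and `phis` length q.")
  }
  if (any(A[upper.tri(A)] != 0)) abort("`A` must be lower triangular.")
  if (any(diag(A) <= 0)) abort("`A` must have a positive diagonal.")
  if (any(phis <= 0)) abort("`phis` must be positive.")
  structure(list(A = A, phis = as.numeric(phis), q = q), class = "lmc_params")
}

#' Stacked LMC cross-covariance over a set of sites
#'
#' Returns the `(n q) x (n q)` covariance matrix of the coefficient fields
#' stacked coefficient-major (all sites for coefficient 1, then coefficient
#' 2, ...): `sum_j (a_j a_j') (x) R_j`, with `a_j` the j-th column of `A` and
#' `R_j` the exponential correlation matrix at decay `phis[j]`. At a single
#' site this reduces to `A A'`.
#'
#' @param sites Data frame with `x`, `y` (km) or coordinate matrix.
#' @param params An [lmc_params()] object.
#' @return A symmetric positive semidefinite `(n q) x (n q)` matrix.
#' @export
lmc_covariance <- function(sites, params) {
  stopifnot(inherits(params, "lmc_params"))
  d <- distance_matrix(sites)
  n <- nrow(d)
  q <- params$q
  out <- matrix(0, n * q, n * q)
  for (j in seq_len(q)) {
    aj <- params$A[, j]
    rj <- exp(-params$phis[j] * d)
    out <- out + kronecker(tcrossprod(aj), rj)
  }
  out
}

#' Draw coefficient fields from the multivariate GP prior
#'
#' @inheritParams lmc_covariance
#' @param mean Length-q mean vector (the domain-wide mean coefficients);
#'   recycled over sites. Default zeros.
#' @param n_draws Number of independent field draws. Default 1.
#' @param seed Optional integer seed.
#' @param jitter Relative diagonal jitter applied before factorization.
#'
#' @return A `n_draws x (n q)` matrix of stacked draws (coefficient-major),
#'   with attribute `"n_sites"`; reshape one draw with
#'   `matrix(draw, n_sites, q)`.
#' @export
sample_mvgp <- function(sites, params, mean = rep(0, params$q), n_draws = 1,
                        seed = NULL, jitter = 1e-8) {
  stopifnot(inherits(params, "lmc_params"))
  if (!is.null(seed)) set.seed(seed)
  sig <- lmc_covariance(sites, params)
  n <- nrow(sig) / params$q
  if (length(mean) != params$q) abort("`mean` must have length q.")
  cu <- chol_jitter(sig, jitter)
  mu <- rep(mean, each = n)
  draws <- matrix(0, n_draws, nrow(sig))
  for (i in seq_len(n_draws)) {
    draws[i, ] <- rmvnorm_chol(cu, mean = mu)
  }
  attr(draws, "n_sites") <- n
  draws
}
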