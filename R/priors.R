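#' Prior configuration for the SVC sampler
#'
#' Weakly informative, scale-aware defaults. Regression means get flat
#' Gaussians; the residual variance an inverse gamma; the spatial decay rates
#' uniform priors whose support is derived from the observed inter-site
#' distances (so every spatial lag present in the data is reachable); the
#' coregionalization matrix half-normal diagonals and normal off-diagonals.
#'
#' @param beta_mean,beta_var Gaussian prior mean and variance for every
#'   regression-mean coefficient (both the domain-wide SVC means and the
#'   fixed coefficients). Defaults 0 and 1e4.
#' @param tau2_shape,tau2_scale Inverse-gamma shape and scale for the
#'   residual variance. Defaults 2 and 0.1.
#' @param phi_lower,phi_upper Uniform prior bounds for each decay rate
#'   (per km). `NULL` (default) derives them at fit time as
#'   `-log(0.05) / d95` and `-log(0.05) / d5`, with `d5`/`d95` the 5th and
#'   95th percentiles of the inter-site distances: supported effective
#'   ranges span the bulk of the observed spatial lags. Range parameters of
#'   spatial processes are weakly identified, so this support choice is part
#'   of the model.
#' @param A_diag_scale Half-normal scale for diagonal coregionalization
#'   elements. Default 1.
#' @param A_offdiag_scale Normal sd for off-diagonal elements. Default 1.
#'
#' @return A list of class `"svc_priors"`.
#' @export
svc_priors <- function(beta_mean = 0, beta_var = 1e4,
                       tau2_shape = 2, tau2_scale = 0.1,
                       phi_lower = NULL, phi_upper = NULL,
                       A_diag_scale = 1, A_offdiag_scale = 1) {
  check_number(beta_var, "beta_var", lower = 0, strict_lower = TRUE)
  check_number(tau2_shape, "tau2_shape", lower = 0, strict_lower = TRUE)
  check_number(tau2_scale, "tau2_scale", lower = 0, strict_lower = TRUE)
  if (!is.null(phi_lower) && !is.null(phi_upper) &&
      (any(phi_lower <= 0) || any(phi_upper <= phi_lower))) {
    abort("Need 0 < phi_lower < phi_upper.")
  }
  structure(
    list(
      beta_mean = beta_mean, beta_var = beta_var,
      tau2_shape = tau2_shape, tau2_scale = tau2_scale,
      phi_lower = phi_lower, phi_upper = phi_upper,
      A_diag_scale = A_diag_scale, A_offdiag_scale = A_offdiag_scale
    ),
    class = "svc_priors"
  )
}

#' MCMC run controls
#'
#' @param n_iter Total iterations. Default 25000.
#' @param n_burn Burn-in iterations discarded before thinning. Default 15000.
#' @param n_thin Keep every `n_thin`-th post-burn-in draw. Default 10.
#' @param seed Optional integer seed; identical configuration plus seed gives
#'   bit-identical chains.
#' @param adapt Adapt Metropolis step sizes during burn-in (Robbins-Monro,
#'   frozen at the end of burn-in so the post-burn-in chain is ergodic).
#'   Default `TRUE`.
#' @param target_accept Acceptance-rate target for adaptation. Default 0.35.
#' @param scale_phi,scale_A Initial random-walk proposal scales for the
#'   log-decay-rate blocks and the coregionalization elements.
#' @param adapt_interval Iterations per adaptation batch. Default 50.
#' @param verbose Print progress every 1000 iterations. Default `FALSE`.
#'
#' @return A list of class `"mcmc_control"`.
#' @export
mcmc_control <- function(n_iter = 25000, n_burn = 15000, n_thin = 10,
                         seed = NULL, adapt = TRUE, target_accept = 0.35,
                         scale_phi = 0.5, scale_A = 0.1,
                         adapt_interval = 50, verbose = FALSE) {
  check_number(n_iter, "n_iter", lower = 1)
  check_number(n_burn, "n_burn", lower = 0, upper = n_iter - 1)
  check_number(n_thin, "n_thin", lower = 1)
  structure(
    list(
      n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
      n_thin = as.integer(n_thin), seed = seed, adapt = isTRUE(adapt),
      target_accept = target_accept, scale_phi = scale_phi,
      scale_A = scale_A, adapt_interval = as.integer(adapt_interval),
      verbose = isTRUE(verbose)
    ),
    class = "mcmc_control"
  )
}
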