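#' Deviance information criterion for a fitted model
#'
#' `D_bar` is the posterior mean of the deviance `-2 log L`; `D_hat` is the
#' deviance at the posterior means of the full parameter set (mean
#' coefficients, residual variance, and — for spatial models — the
#' site-level coefficient fields); `pD = D_bar - D_hat` is the effective
#' number of parameters and `DIC = D_bar + pD`. Lower DIC indicates better
#' fit after the complexity penalty.
#'
#' @param fit An `svc_fit`.
#' @param frame The `svc_frame` the model was fitted to.
#' @return A one-row tibble with columns `D_bar`, `D_hat`, `pD`, `DIC`.
#' @export
compute_dic <- function(fit, frame) {
  stopifnot(inherits(fit, "svc_fit"), inherits(frame, "svc_frame"))
  y <- frame$response
  Xs <- frame$design_svc
  Xf <- frame$design_fixed
  n_draws <- length(fit$samples$tau2)
  if (fit$spatial) {
    site_map <- match(frame$sites$lake_id, fit$sites$lake_id)
    if (anyNA(site_map)) abort("Frame contains lakes unknown to the fit.")
    row_site <- site_map[frame$site_index]
  }
  dev <- numeric(n_draws)
  for (i in seq_len(n_draws)) {
    mu <- draw_predictor(fit, i, Xs, Xf,
                         if (fit$spatial) row_site else NULL)
    dev[i] <- -2 * sum(stats::dnorm(y, mu, sqrt(fit$samples$tau2[i]),
                                    log = TRUE))
  }
  d_bar <- mean(dev)

  beta_mu_hat <- colMeans(fit$samples$beta_mu)
  beta_fixed_hat <- colMeans(fit$samples$beta_fixed)
  tau2_hat <- mean(fit$samples$tau2)
  if (fit$spatial) {
    coeff_hat <- apply(fit$samples$site_coeffs, c(2, 3), mean)
    mu_hat <- rowSums(Xs * coeff_hat[row_site, , drop = FALSE])
  } else {
    mu_hat <- drop(Xs %*% beta_mu_hat)
  }
  if (ncol(Xf) > 0) mu_hat <- mu_hat + drop(Xf %*% beta_fixed_hat)
  d_hat <- -2 * sum(stats::dnorm(y, mu_hat, sqrt(tau2_hat), log = TRUE))
  tibble(D_bar = d_bar, D_hat = d_hat, pD = d_bar - d_hat,
         DIC = d_bar + (d_bar - d_hat))
}

draw_predictor <- function(fit, i, Xs, Xf, row_site) {
  if (fit$spatial) {
    q <- length(fit$svc_terms)
    coeffs <- matrix(fit$samples$site_coeffs[i, , ],
                     nrow = nrow(fit$sites), ncol = q)
    mu <- rowSums(Xs * coeffs[row_site, , drop = FALSE])
  } else {
    mu <- drop(Xs %*% fit$samples$beta_mu[i, ])
  }
  if (ncol(Xf) > 0) mu <- mu + drop(Xf %*% fit$samples$beta_fixed[i, ])
  mu
}

#' Continuous ranked probability score for a Gaussian predictive distribution
#'
#' Closed form: `sigma * (z * (2 * Phi(z) - 1) + 2 * phi(z) - 1/sqrt(pi))`
#' with `z = (y - mean) / sd`. Smaller is better; the score is in the units
#' of the response.
#'
#' @param y Observed value(s).
#' @param mean,sd Predictive mean(s) and standard deviation(s); `sd > 0`.
#' @return Score(s), nonnegative.
#' @examples
#' crps_gaussian(0, 0, 1) # 0.23369...
#' @export
crps_gaussian <- function(y, mean = 0, sd = 1) {
  if (any(sd <= 0)) abort("`sd` must be positive.")
  z <- (y - mean) / sd
  sd * (z * (2 * stats::pnorm(z) - 1) + 2 * stats::dnorm(z) - 1 / sqrt(pi))
}

#' Sample-based CRPS estimator
#'
#' `mean(|X - y|) - mean(|X - X'|) / 2` over a predictive sample, for use
#' when predictive draws are not Gaussian. Computed via the sorted-sample
#' identity in O(n log n).
#'
#' @param y A single observed value.
#' @param draws Numeric vector of predictive draws.
#' @return The estimated score.
#' @export
crps_sample <- function(y, draws) {
  n <- length(draws)
  if (n < 2) abort("Need at least 2 draws.")
  xs <- sort(draws)
  term1 <- mean(abs(xs - y))
  # sum over all ordered pairs |x_i - x_j| = 2 * sum_k (2k - n - 1) x_(k)
  term2 <- 2 * sum((2 * seq_len(n) - n - 1) * xs) / n^2
  term1 - term2 / 2
}

#' Predictive scores for a holdout set
#'
#' Summarizes a posterior predictive sample against held-out observations on
#' the modeling (log10) scale: root mean-square prediction error of the
#' predictive means (RMSPE), mean sample-based CRPS, the percentage of
#' observations inside their central 95% predictive interval (PCI), and the
#' mean width of those intervals (PIW).
#'
#' @param pred A draws x observations matrix from [posterior_predict()]
#'   (at least 100 draws per observation).
#' @param observed Observed responses; defaults to the `"observed"`
#'   attribute attached by [posterior_predict()]. An `svc_frame` may also be
#'   given.
#' @param interval Central interval mass for PCI/PIW. Default 0.95.
#' @return A one-row tibble with `rmspe`, `crps`, `pci`, `piw`.
#' @export
score_holdout <- function(pred, observed = NULL, interval = 0.95) {
  if (is.null(observed)) observed <- attr(pred, "observed")
  if (inherits(observed, "svc_frame")) observed <- observed$response
  if (is.null(observed)) abort("No observed responses supplied.")
  pred <- unclass(pred)
  if (ncol(pred) != length(observed)) {
    abort("`pred` columns must match the observations.")
  }
  if (nrow(pred) < 100) {
    warn("Fewer than 100 predictive draws per observation.")
  }
  alpha <- (1 - interval) / 2
  means <- colMeans(pred)
  qs <- apply(pred, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  tibble(
    rmspe = sqrt(mean((means - observed)^2)),
    crps = mean(vapply(seq_along(observed),
                       function(i) crps_sample(observed[i], pred[, i]),
                       numeric(1))),
    pci = 100 * mean(observed >= qs[1, ] & observed <= qs[2, ]),
    piw = mean(qs[2, ] - qs[1, ])
  )
}
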