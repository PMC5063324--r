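#' Tidy posterior parameter summaries of an SVC fit
#'
#' One row per scalar parameter: the domain-wide SVC means, fixed
#' coefficients, residual variance, and — for spatial fits — decay rates and
#' their implied effective spatial ranges (km, distance at which correlation
#' drops to 0.05). `estimate` is the posterior mean except for effective
#' ranges, where the posterior median is reported (ranges are a heavy-tailed
#' transform of the decay rate).
#'
#' @param x An `svc_fit`.
#' @param conf_level Credible-interval mass. Default 0.95.
#' @param ... Unused.
#' @return A tibble with `term`, `type`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `rhat`.
#' @method tidy svc_fit
#' @export
tidy.svc_fit <- function(x, conf_level = 0.95, ...) {
  alpha <- (1 - conf_level) / 2
  summarize_chain <- function(draws, term, type, use_median = FALSE) {
    tibble(
      term = term,
      type = type,
      estimate = if (use_median) stats::median(draws) else mean(draws),
      std.error = stats::sd(draws),
      conf.low = unname(stats::quantile(draws, alpha)),
      conf.high = unname(stats::quantile(draws, 1 - alpha))
    )
  }
  s <- x$samples
  out <- bind_rows(
    purrr::map(seq_along(x$svc_terms), function(j) {
      summarize_chain(s$beta_mu[, j], x$svc_terms[j], "svc_mean")
    }),
    purrr::map(seq_along(x$fixed_terms), function(j) {
      summarize_chain(s$beta_fixed[, j], x$fixed_terms[j], "fixed")
    }),
    list(summarize_chain(s$tau2, "tau2", "variance"))
  )
  if (x$spatial) {
    out <- bind_rows(
      out,
      purrr::map(seq_along(x$svc_terms), function(j) {
        summarize_chain(s$phis[, j], paste0("phi_", x$svc_terms[j]), "decay")
      }),
      purrr::map(seq_along(x$svc_terms), function(j) {
        summarize_chain(effective_range(s$phis[, j]),
                        paste0("eff_range_", x$svc_terms[j]), "range",
                        use_median = TRUE)
      })
    )
  }
  left_join(out, x$diagnostics, by = "term")
}

#' One-row fit summary
#'
#' @param x An `svc_fit`.
#' @param ... Unused.
#' @return A tibble with observation/site/draw counts, whether coefficients
#'   vary spatially, the posterior mean log likelihood, and the largest
#'   split-chain Rhat among scalar parameters.
#' @method glance svc_fit
#' @export
glance.svc_fit <- function(x, ...) {
  tibble(
    n_obs = x$n_obs,
    n_sites = if (x$spatial) nrow(x$sites) else NA_integer_,
    n_draws = length(x$samples$tau2),
    spatial = x$spatial,
    mean_log_lik = mean(x$samples$log_lik),
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE)
  )
}
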