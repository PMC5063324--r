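#' Posterior predictive draws for holdout observations
#'
#' Composition sampling: for each retained posterior draw, holdout rows get
#' one predictive draw `y* ~ N(linear predictor, tau2)`. Holdout lakes that
#' were part of the training site set use their sampled coefficient fields;
#' unobserved lakes get coefficients kriged from the multivariate GP
#' conditional — each latent process is conditioned on its training-site
#' realization under that draw's decay rate, so a far-away lake reverts to
#' the domain-wide mean coefficients with full marginal variance.
#'
#' @param fit An [fit_svc()] or [fit_nonspatial()] object.
#' @param holdout An `svc_frame` of holdout observations (same design
#'   columns as the training frame).
#' @param n_draws Number of retained posterior draws to use (evenly
#'   subsampled); default all.
#' @param seed Optional integer seed for the predictive noise.
#'
#' @return A `n_draws x n_holdout` matrix of predictive draws on the log10
#'   chlorophyll scale, with the observed responses attached as attribute
#'   `"observed"`. Feed to [score_holdout()].
#' @export
posterior_predict <- function(fit, holdout, n_draws = NULL, seed = NULL) {
  stopifnot(inherits(fit, "svc_fit"), inherits(holdout, "svc_frame"))
  if (!is.null(seed)) set.seed(seed)
  total <- length(fit$samples$tau2)
  if (is.null(n_draws)) n_draws <- total
  if (n_draws < 1 || n_draws > total) {
    abort(sprintf("`n_draws` must be in [1, %d].", total))
  }
  use <- unique(round(seq(1, total, length.out = n_draws)))
  n_hold <- length(holdout$response)
  q <- length(fit$svc_terms)
  Xs <- holdout$design_svc
  Xf <- holdout$design_fixed
  out <- matrix(NA_real_, length(use), n_hold)

  if (!fit$spatial) {
    Z <- cbind(Xs, Xf)
    for (t in seq_along(use)) {
      i <- use[t]
      gam <- c(fit$samples$beta_mu[i, ], fit$samples$beta_fixed[i, ])
      mu <- drop(Z %*% gam)
      out[t, ] <- stats::rnorm(n_hold, mu, sqrt(fit$samples$tau2[i]))
    }
  } else {
    train_sites <- fit$sites
    hold_site_of_row <- holdout$site_index
    hold_sites <- holdout$sites
    obs_match <- match(hold_sites$lake_id, train_sites$lake_id)
    is_new <- is.na(obs_match)
    d_oo <- distance_matrix(train_sites)
    if (any(is_new)) {
      new_xy <- hold_sites[is_new, , drop = FALSE]
      d_no <- cross_distance(new_xy, train_sites)
      d_nn <- distance_matrix(new_xy)
      n_new <- sum(is_new)
    }
    for (t in seq_along(use)) {
      i <- use[t]
      beta_mu <- fit$samples$beta_mu[i, ]
      beta_fixed <- fit$samples$beta_fixed[i, ]
      tau2 <- fit$samples$tau2[i]
      phis <- fit$samples$phis[i, ]
      A <- lower_tri_from(fit$samples$A_elements[i, ], q)
      v_train <- matrix(fit$samples$v[i, , ], nrow = nrow(train_sites), ncol = q)
      w_hold <- matrix(0, nrow(hold_sites), q)
      w_hold[!is_new, ] <- v_train[obs_match[!is_new], , drop = FALSE]
      if (any(is_new)) {
        for (j in seq_len(q)) {
          r_oo <- exp(-phis[j] * d_oo)
          cu <- chol_jitter(r_oo)
          c_no <- exp(-phis[j] * d_no)
          alpha <- backsolve(cu, backsolve(cu, v_train[, j],
                                           transpose = TRUE))
          cond_mean <- drop(c_no %*% alpha)
          half <- backsolve(cu, t(c_no), transpose = TRUE)
          cond_cov <- exp(-phis[j] * d_nn) - crossprod(half)
          cu_n <- chol_jitter(cond_cov, jitter = 1e-6)
          w_hold[is_new, j] <- cond_mean +
            drop(crossprod(cu_n, stats::rnorm(n_new)))
        }
      }
      coeffs <- sweep(w_hold %*% t(A), 2, beta_mu, `+`)
      mu <- rowSums(Xs * coeffs[hold_site_of_row, , drop = FALSE])
      if (ncol(Xf) > 0) mu <- mu + drop(Xf %*% beta_fixed)
      out[t, ] <- stats::rnorm(n_hold, mu, sqrt(tau2))
    }
  }
  attr(out, "observed") <- holdout$response
  class(out) <- c("svc_predictive", class(out))
  out
}

cross_distance <- function(a, b) {
  sqrt(outer(a$x, b$x, `-`)^2 + outer(a$y, b$y, `-`)^2)
}

lower_tri_from <- function(elements, q) {
  A <- matrix(0, q, q)
  idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  A[idx] <- elements
  A
}
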