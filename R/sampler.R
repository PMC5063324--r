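#' Gaussian log likelihood of the SVC model
#'
#' Sum over observations of the normal log density of the response minus the
#' spatially-varying and fixed linear predictors, with residual variance
#' `tau2`.
#'
#' @param frame An `svc_frame`.
#' @param beta_mu Length-q domain-wide mean coefficients for the SVC terms.
#' @param beta_fixed Length-p fixed coefficients (may be `NULL` when the
#'   frame has no fixed design).
#' @param site_coeffs Optional `n_sites x q` matrix of site-level
#'   coefficients `b~(s)`; if `NULL`, coefficients are constant at `beta_mu`
#'   (the non-spatial model).
#' @param tau2 Residual variance, positive.
#' @return A single number.
#' @export
svc_log_likelihood <- function(frame, beta_mu, beta_fixed = NULL,
                               site_coeffs = NULL, tau2) {
  stopifnot(inherits(frame, "svc_frame"))
  check_number(tau2, "tau2", lower = 0, strict_lower = TRUE)
  q <- ncol(frame$design_svc)
  if (is.null(site_coeffs)) {
    site_coeffs <- matrix(beta_mu, nrow(frame$sites), q, byrow = TRUE)
  }
  mu <- rowSums(frame$design_svc * site_coeffs[frame$site_index, , drop = FALSE])
  if (ncol(frame$design_fixed) > 0) {
    mu <- mu + drop(frame$design_fixed %*% beta_fixed)
  }
  sum(stats::dnorm(frame$response, mu, sqrt(tau2), log = TRUE))
}

# ---- conditional update kernels (internal; shared by fit_svc / fit_nonspatial)

# Conjugate Gaussian draw of all mean coefficients gamma = (beta_mu, beta)
# given the SVC field contribution `svc_pred` and tau2. With vague priors and
# no SVC contribution, the conditional mean is the least-squares solution.
update_gamma <- function(y, Z, ZtZ, svc_pred, tau2, prior_mean, prior_prec) {
  r <- y - svc_pred
  Q <- ZtZ / tau2 + diag(prior_prec, ncol(Z))
  b <- crossprod(Z, r) / tau2 + prior_prec * prior_mean
  cu <- chol(Q)
  mean <- backsolve(cu, backsolve(cu, b, transpose = TRUE))
  drop(mean + backsolve(cu, stats::rnorm(ncol(Z))))
}

# Inverse-gamma draw of the residual variance given the residual vector.
update_tau2 <- function(resid, shape, scale) {
  rinvgamma(1, shape + length(resid) / 2, scale + sum(resid^2) / 2)
}

# Joint conditional Gaussian draw of the stacked latent processes v
# (process-major). Prior precision is block-diagonal in the R_j inverses;
# the data add site-diagonal precision through the latent design U = Xs A.
update_v <- function(r2, U, site, m, tau2, P0) {
  q <- ncol(U)
  Q <- P0
  b <- numeric(m * q)
  for (j in seq_len(q)) {
    idx_j <- (j - 1L) * m
    b[idx_j + seq_len(m)] <- rowsum_all(U[, j] * r2, site, m) / tau2
    for (k in j:q) {
      s_jk <- rowsum_all(U[, j] * U[, k], site, m) / tau2
      ii <- idx_j + seq_len(m)
      jj <- (k - 1L) * m + seq_len(m)
      Q[cbind(ii, jj)] <- Q[cbind(ii, jj)] + s_jk
      if (k > j) Q[cbind(jj, ii)] <- Q[cbind(jj, ii)] + s_jk
    }
  }
  cu <- chol(Q)
  mean <- backsolve(cu, backsolve(cu, b, transpose = TRUE))
  v <- drop(mean + backsolve(cu, stats::rnorm(m * q)))
  matrix(v, m, q)
}

# rowsum over site indices 1..m, returning a dense length-m vector.
rowsum_all <- function(x, site, m) {
  out <- numeric(m)
  agg <- rowsum(x, site)
  out[as.integer(rownames(agg))] <- agg
  out
}

# Gaussian log density of a unit-variance GP realization given the upper
# Cholesky factor of its correlation matrix (up to the 2*pi constant).
gp_logdens <- function(v_j, chol_upper) {
  z <- backsolve(chol_upper, v_j, transpose = TRUE)
  -sum(log(diag(chol_upper))) - 0.5 * sum(z^2)
}

#' Fit the spatially-varying coefficient model by Metropolis-within-Gibbs
#'
#' Samples the posterior of the model
#' `y_t(s) = x~_t(s)' b~(s) + x_t(s)' b + e_t(s)`, `e ~ N(0, tau2)`, where
#' the site-level coefficients `b~(s)` follow a multivariate Gaussian process
#' with a linear-model-of-coregionalization covariance (independent latent
#' exponential-correlation processes mixed by a lower-triangular `A`). Each
#' iteration updates, in order: the mean coefficients (conjugate Gaussian),
#' the latent coefficient fields (joint conditional Gaussian), the residual
#' variance (inverse gamma), each decay rate `phi_j` (random-walk Metropolis
#' on the log scale, conditional on its latent process), and each element of
#' `A` (random-walk Metropolis with likelihood-only data contribution).
#'
#' @param frame An [build_model_frame()] result (the training partition).
#' @param priors An [svc_priors()] configuration.
#' @param control An [mcmc_control()] configuration.
#'
#' @return An object of class `"svc_fit"` carrying thinned post-burn-in
#'   chains (`beta_mu`, `beta_fixed`, `tau2`, `phis`, `A_elements`,
#'   `site_coeffs`, latent `v`, log-likelihood trace), per-block acceptance
#'   rates, split-chain Rhat diagnostics, and the fitting metadata needed for
#'   prediction. Summarize with [tidy()], [glance()] or [coefficient_field()].
#' @examples
#' obs <- simulate_lakes(sim_config(n_sites = 25, n_extra_lakes = 0), seed = 2)
#' frame <- build_model_frame(obs$data)
#' fit <- fit_svc(frame, control = mcmc_control(n_iter = 200, n_burn = 100,
#'                                              n_thin = 2, seed = 1))
#' tidy(fit)
#' @export
fit_svc <- function(frame, priors = svc_priors(), control = mcmc_control()) {
  run_sampler(frame, priors, control, spatial = TRUE)
}

#' Fit the non-spatial Bayesian regression benchmark
#'
#' The first candidate model: an ordinary linear regression of log10
#' chlorophyll on log10 TP and log10 color (plus any fixed covariates in the
#' frame), with constant coefficients. Gibbs sampling alternates the
#' conjugate Gaussian coefficient draw and the inverse-gamma variance draw;
#' under the vague default priors the coefficient posterior means approach
#' the least-squares estimates.
#'
#' @inheritParams fit_svc
#' @return An `"svc_fit"` object with `spatial = FALSE` (no site-level
#'   coefficient chains).
#' @export
fit_nonspatial <- function(frame, priors = svc_priors(),
                           control = mcmc_control()) {
  run_sampler(frame, priors, control, spatial = FALSE)
}

run_sampler <- function(frame, priors, control, spatial) {
  stopifnot(inherits(frame, "svc_frame"), inherits(priors, "svc_priors"),
            inherits(control, "mcmc_control"))
  if (!is.null(control$seed)) set.seed(control$seed)

  y <- frame$response
  Xs <- frame$design_svc
  Xf <- frame$design_fixed
  Z <- cbind(Xs, Xf)
  n <- length(y)
  q <- ncol(Xs)
  p <- ncol(Xf)
  site <- frame$site_index
  m <- nrow(frame$sites)

  ls_fit <- stats::lm.fit(Z, y)
  if (any(is.na(ls_fit$coefficients))) {
    abort(paste0(
      "Singular design; collinear column(s): ",
      paste(colnames(Z)[is.na(ls_fit$coefficients)], collapse = ", ")
    ))
  }
  gamma <- ls_fit$coefficients
  resid0 <- ls_fit$residuals
  tau2 <- max(stats::var(resid0), 1e-6)
  ZtZ <- crossprod(Z)
  prior_prec <- 1 / priors$beta_var
  prior_mean <- priors$beta_mean

  if (spatial) {
    dmat <- distance_matrix(frame$sites)
    dpos <- dmat[upper.tri(dmat)]
    dpos <- dpos[dpos > 0]
    if (length(dpos) == 0) abort("All sites are coincident; cannot fit a spatial model.")
    dq <- stats::quantile(dpos, c(0.05, 0.95), names = FALSE)
    phi_lo <- if (is.null(priors$phi_lower)) -log(0.05) / dq[2] else priors$phi_lower
    phi_hi <- if (is.null(priors$phi_upper)) -log(0.05) / dq[1] else priors$phi_upper
    phi_lo <- rep_len(phi_lo, q)
    phi_hi <- rep_len(phi_hi, q)
    phis <- exp((log(phi_lo) + log(phi_hi)) / 2)
    A <- diag(rep(0.5 * stats::sd(resid0), q))
    v <- matrix(0, m, q)
    cholR <- Rinv <- vector("list", q)
    P0 <- matrix(0, m * q, m * q)
    for (j in seq_len(q)) {
      cholR[[j]] <- chol_jitter(exp(-phis[j] * dmat))
      Rinv[[j]] <- chol2inv(cholR[[j]])
      blk <- (j - 1L) * m + seq_len(m)
      P0[blk, blk] <- Rinv[[j]]
    }
    A_idx <- which(lower.tri(A, diag = TRUE), arr.ind = TRUE)
    A_idx <- A_idx[order(A_idx[, 2], A_idx[, 1]), , drop = FALSE]
    n_a <- nrow(A_idx)
    scale_phi <- rep(control$scale_phi, q)
    scale_A <- rep(control$scale_A, n_a)
    acc <- batch_acc <- setNames(
      numeric(q + n_a),
      c(paste0("phi_", colnames(Xs)),
        paste0("A_", A_idx[, 1], A_idx[, 2]))
    )
    batch_n <- 0
    U <- Xs %*% A
    svc_pred <- rowSums(U * v[site, , drop = FALSE])
  } else {
    svc_pred <- numeric(n)
    acc <- numeric(0)
  }

  keep <- seq.int(control$n_burn + control$n_thin, control$n_iter,
                  by = control$n_thin)
  if (control$n_iter == control$n_burn + 1L) keep <- control$n_iter
  n_keep <- length(keep)
  if (n_keep < 1) abort("No retained draws; increase n_iter or reduce n_thin.")
  out_gamma <- matrix(NA_real_, n_keep, q + p)
  colnames(out_gamma) <- c(colnames(Xs), colnames(Xf))
  out_tau2 <- numeric(n_keep)
  out_loglik <- numeric(n_keep)
  if (spatial) {
    out_phis <- matrix(NA_real_, n_keep, q,
                       dimnames = list(NULL, paste0("phi_", colnames(Xs))))
    out_A <- matrix(NA_real_, n_keep, n_a)
    colnames(out_A) <- paste0("A_", A_idx[, 1], A_idx[, 2])
    out_v <- array(NA_real_, c(n_keep, m, q))
    out_coeffs <- array(NA_real_, c(n_keep, m, q))
  }

  kept <- 0L
  n_batches <- 0
  for (iter in seq_len(control$n_iter)) {
    gamma <- update_gamma(y, Z, ZtZ, svc_pred, tau2, prior_mean, prior_prec)
    fixed_pred <- drop(Z %*% gamma)

    if (spatial) {
      r2 <- y - fixed_pred
      v <- update_v(r2, U, site, m, tau2, P0)
      svc_pred <- rowSums(U * v[site, , drop = FALSE])
    }

    resid <- y - fixed_pred - svc_pred
    tau2 <- update_tau2(resid, priors$tau2_shape, priors$tau2_scale)

    if (spatial) {
      # phi_j: random walk on log phi, accepted by the likelihood with the
      # j-th latent process integrated out (collapsed move); on acceptance
      # the process is redrawn from its conditional under the new phi. The
      # uncollapsed variant (conditioning on the sampled field) mixes
      # poorly between short- and long-range modes.
      for (j in seq_len(q)) {
        lphi_new <- log(phis[j]) + stats::rnorm(1, 0, scale_phi[j])
        phi_new <- exp(lphi_new)
        if (phi_new >= phi_lo[j] && phi_new <= phi_hi[j]) {
          u_j <- U[, j]
          pred_other <- svc_pred - u_j * v[site, j]
          r_j <- y - fixed_pred - pred_other
          s_j <- rowsum_all(u_j^2, site, m) / tau2
          b_j <- rowsum_all(u_j * r_j, site, m) / tau2
          marg <- function(chol_r, r_inv) {
            mmat <- r_inv
            diag(mmat) <- diag(mmat) + s_j
            chol_m <- chol(mmat)
            half <- backsolve(chol_m, b_j, transpose = TRUE)
            list(
              ll = -sum(log(diag(chol_r))) - sum(log(diag(chol_m))) +
                0.5 * sum(half^2),
              chol_m = chol_m
            )
          }
          chol_new <- chol_jitter(exp(-phi_new * dmat))
          rinv_new <- chol2inv(chol_new)
          cur <- marg(cholR[[j]], Rinv[[j]])
          prop <- marg(chol_new, rinv_new)
          lr <- prop$ll - cur$ll + lphi_new - log(phis[j])
          if (is.finite(lr) && log(stats::runif(1)) < lr) {
            phis[j] <- phi_new
            cholR[[j]] <- chol_new
            Rinv[[j]] <- rinv_new
            blk <- (j - 1L) * m + seq_len(m)
            P0[blk, blk] <- rinv_new
            cm <- prop$chol_m
            v[, j] <- backsolve(cm, backsolve(cm, b_j, transpose = TRUE)) +
              backsolve(cm, stats::rnorm(m))
            svc_pred <- pred_other + u_j * v[site, j]
            resid <- y - fixed_pred - svc_pred
            acc[j] <- acc[j] + 1
            batch_acc[j] <- batch_acc[j] + 1
          }
        }
      }
      # A elements | v, data: likelihood ratio plus element prior
      ssr <- sum(resid^2)
      for (e in seq_len(n_a)) {
        l <- A_idx[e, 1]; jj <- A_idx[e, 2]
        a_cur <- A[l, jj]
        on_diag <- l == jj
        if (on_diag) {
          a_new <- exp(log(a_cur) + stats::rnorm(1, 0, scale_A[e]))
        } else {
          a_new <- a_cur + stats::rnorm(1, 0, scale_A[e])
        }
        delta <- (a_new - a_cur) * Xs[, l] * v[site, jj]
        resid_new <- resid - delta
        ssr_new <- sum(resid_new^2)
        lr <- -(ssr_new - ssr) / (2 * tau2)
        if (on_diag) {
          lr <- lr - (a_new^2 - a_cur^2) / (2 * priors$A_diag_scale^2) +
            log(a_new) - log(a_cur)
        } else {
          lr <- lr - (a_new^2 - a_cur^2) / (2 * priors$A_offdiag_scale^2)
        }
        if (is.finite(lr) && log(stats::runif(1)) < lr) {
          A[l, jj] <- a_new
          resid <- resid_new
          ssr <- ssr_new
          acc[q + e] <- acc[q + e] + 1
          batch_acc[q + e] <- batch_acc[q + e] + 1
        }
      }
      U <- Xs %*% A
      svc_pred <- rowSums(U * v[site, , drop = FALSE])

      # Robbins-Monro step-size adaptation, burn-in only
      batch_n <- batch_n + 1
      if (control$adapt && iter <= control$n_burn &&
          batch_n == control$adapt_interval) {
        n_batches <- n_batches + 1
        step <- min(0.25, 1 / sqrt(n_batches))
        rate <- batch_acc / batch_n
        scale_phi <- scale_phi *
          exp(step * (rate[seq_len(q)] - control$target_accept))
        scale_A <- scale_A *
          exp(step * (rate[q + seq_len(n_a)] - control$target_accept))
        batch_acc[] <- 0
        batch_n <- 0
      }
    }

    if (kept < n_keep && iter == keep[kept + 1L]) {
      kept <- kept + 1L
      out_gamma[kept, ] <- gamma
      out_tau2[kept] <- tau2
      ll <- sum(stats::dnorm(y, fixed_pred + svc_pred, sqrt(tau2), log = TRUE))
      if (!is.finite(ll)) {
        abort(sprintf(
          "Divergent chain at iteration %d (non-finite log density; tau2 = %g).",
          iter, tau2
        ))
      }
      out_loglik[kept] <- ll
      if (spatial) {
        out_phis[kept, ] <- phis
        out_A[kept, ] <- A[A_idx]
        out_v[kept, , ] <- v
        out_coeffs[kept, , ] <- sweep(v %*% t(A), 2, gamma[seq_len(q)], `+`)
      }
    }
    if (control$verbose && iter %% 1000 == 0) {
      message(sprintf("iter %d / %d", iter, control$n_iter))
    }
  }

  samples <- list(
    beta_mu = out_gamma[, seq_len(q), drop = FALSE],
    beta_fixed = out_gamma[, q + seq_len(p), drop = FALSE],
    tau2 = out_tau2,
    log_lik = out_loglik
  )
  if (spatial) {
    samples$phis <- out_phis
    samples$A_elements <- out_A
    samples$v <- out_v
    samples$site_coeffs <- out_coeffs
  }
  scalar_chains <- cbind(
    out_gamma, tau2 = out_tau2,
    if (spatial) out_phis else NULL
  )
  diagnostics <- tibble(
    term = colnames(scalar_chains),
    rhat = apply(scalar_chains, 2, split_rhat)
  )
  structure(
    list(
      samples = samples,
      spatial = spatial,
      svc_terms = colnames(Xs),
      fixed_terms = colnames(Xf),
      sites = frame$sites,
      acceptance = if (spatial) acc / control$n_iter else NULL,
      diagnostics = diagnostics,
      priors = priors,
      control = control,
      phi_bounds = if (spatial) list(lower = phi_lo, upper = phi_hi) else NULL,
      n_obs = n
    ),
    class = "svc_fit"
  )
}

#' @export
print.svc_fit <- function(x, ...) {
  cat(sprintf(
    "<svc_fit> %s model: %d observations%s, %d retained draws\n",
    if (x$spatial) "spatially-varying coefficient" else "non-spatial",
    x$n_obs,
    if (x$spatial) sprintf(" at %d sites", nrow(x$sites)) else "",
    length(x$samples$tau2)
  ))
  print(tidy(x), n = 15)
  invisible(x)
}
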