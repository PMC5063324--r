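test_that("log likelihood matches the Gaussian density formula", {
  frame <- build_model_frame(tiny_obs())
  n <- length(frame$response)
  q <- 3

  # perfect fit: residuals all zero, tau2 = 1
  coeffs <- matrix(0, nrow(frame$sites), q)
  # choose site intercepts reproducing y exactly for a single-row-per-site case
  one <- tiny_obs(3, lakes = 3)
  f1 <- build_model_frame(one)
  exact <- cbind(f1$response - f1$design_svc[, 2] - f1$design_svc[, 3], 1, 1)
  expect_equal(
    svc_log_likelihood(f1, beta_mu = c(0, 0, 0), site_coeffs = exact, tau2 = 1),
    3 * log(1 / sqrt(2 * pi))
  )

  # single row with residual 1
  r1 <- build_model_frame(tiny_obs(1))
  sc <- cbind(r1$response - 1, 0, 0)
  expect_equal(
    svc_log_likelihood(r1, beta_mu = c(0, 0, 0),
                       site_coeffs = sc * c(1, 0, 0), tau2 = 1),
    -0.5 - 0.5 * log(2 * pi)
  )

  # random frame vs direct summation oracle
  set.seed(2)
  beta_mu <- rnorm(3)
  tau2 <- 0.7
  coeffs <- matrix(rnorm(nrow(frame$sites) * q, sd = 0.3), ncol = q) +
    matrix(beta_mu, nrow(frame$sites), q, byrow = TRUE)
  mu <- rowSums(frame$design_svc * coeffs[frame$site_index, ])
  oracle <- sum(-0.5 * log(2 * pi * tau2) -
                  (frame$response - mu)^2 / (2 * tau2))
  expect_equal(
    svc_log_likelihood(frame, beta_mu, site_coeffs = coeffs, tau2 = tau2),
    oracle, tolerance = 1e-10
  )
  expect_error(svc_log_likelihood(frame, beta_mu, site_coeffs = coeffs,
                                  tau2 = -1), "tau2")
})

test_that("mean-coefficient update is the conjugate Gaussian", {
  set.seed(11)
  n <- 6
  Z <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(Z %*% c(0.5, 1.2, -0.7)) + rnorm(n, sd = 0.3)
  ols <- unname(lm.fit(Z, y)$coefficients)

  # vague prior, tiny residual variance: draw pinned to the least-squares fit
  draw <- svclake:::update_gamma(y, Z, crossprod(Z), numeric(n),
                                 tau2 = 1e-12, prior_mean = 0,
                                 prior_prec = 1e-8)
  expect_equal(unname(draw), ols, tolerance = 1e-4)

  # empirical mean of repeated draws matches the conditional mean
  tau2 <- 0.4
  draws <- t(replicate(5000, svclake:::update_gamma(
    y, Z, crossprod(Z), numeric(n), tau2, 0, 1e-4
  )))
  Q <- crossprod(Z) / tau2 + diag(1e-4, 3)
  cond_mean <- drop(solve(Q, crossprod(Z, y) / tau2))
  mc_se <- sqrt(diag(solve(Q)) / 5000)
  expect_true(all(abs(colMeans(draws) - cond_mean) < 4 * mc_se))

  # degenerate prior pins the draw at the prior mean
  pinned <- svclake:::update_gamma(y, Z, crossprod(Z), numeric(n),
                                   tau2 = 1, prior_mean = 0.25,
                                   prior_prec = 1e12)
  expect_equal(unname(pinned), rep(0.25, 3), tolerance = 1e-4)
})

test_that("residual variance update is the inverse-gamma conditional", {
  set.seed(3)
  # zero residuals: shape grows by n/2, scale unchanged
  n <- 40
  draws0 <- replicate(10000, svclake:::update_tau2(numeric(n), 2, 0.1))
  expect_equal(mean(draws0), 0.1 / (2 + n / 2 - 1), tolerance = 0.02)

  # closed-form mean with residuals
  resid <- rnorm(200, sd = 0.8)
  shape <- 2 + 100
  scale <- 0.1 + sum(resid^2) / 2
  draws <- replicate(10000, svclake:::update_tau2(resid, 2, 0.1))
  expect_equal(mean(draws), scale / (shape - 1), tolerance = 0.02)

  # with large n the draws concentrate at SSR / n
  big <- rnorm(20000, sd = sqrt(0.63))
  d <- replicate(200, svclake:::update_tau2(big, 2, 0.1))
  expect_equal(mean(d), mean(big^2), tolerance = 0.02)
})

test_that("latent field update matches the scalar conjugate posterior", {
  # one site, one observation, one process
  set.seed(21)
  u <- 1.7
  r2 <- 0.9
  tau2 <- 0.5
  P0 <- matrix(1)  # unit prior precision (R = 1)
  draws <- replicate(6000, svclake:::update_v(r2, matrix(u), 1L, 1L, tau2, P0)[1, 1])
  prec <- 1 + u^2 / tau2
  cond_mean <- (u * r2 / tau2) / prec
  expect_equal(mean(draws), cond_mean, tolerance = 5 / sqrt(6000))
  expect_equal(var(draws), 1 / prec, tolerance = 0.1)

  # no-data limit: enormous tau2 reverts to the GP prior
  prior_draws <- replicate(6000,
                           svclake:::update_v(r2, matrix(u), 1L, 1L, 1e12, P0)[1, 1])
  expect_equal(mean(prior_draws), 0, tolerance = 0.05)
  expect_equal(var(prior_draws), 1, tolerance = 0.1)
})

test_that("latent field update reproduces the analytic conditional on a toy", {
  set.seed(31)
  m <- 3
  sites <- tibble::tibble(x = c(0, 8, 30), y = c(0, 3, -4))
  R <- exp(-0.08 * distance_matrix(sites))
  q <- 2
  n <- 7
  site <- c(1L, 1L, 2L, 2L, 3L, 3L, 3L)
  U <- matrix(rnorm(n * q), n, q)
  r2 <- rnorm(n)
  tau2 <- 0.6
  Rinv <- solve(R)
  P0 <- matrix(0, m * q, m * q)
  P0[1:m, 1:m] <- Rinv
  P0[m + 1:m, m + 1:m] <- Rinv
  # analytic conditional
  B <- matrix(0, n, m * q)
  for (i in seq_len(n)) {
    for (j in seq_len(q)) B[i, (j - 1) * m + site[i]] <- U[i, j]
  }
  Q <- P0 + crossprod(B) / tau2
  cond_cov <- solve(Q)
  cond_mean <- drop(cond_cov %*% crossprod(B, r2) / tau2)

  draws <- t(replicate(4000, as.vector(
    svclake:::update_v(r2, U, site, m, tau2, P0)
  )))
  expect_lt(max(abs(colMeans(draws) - cond_mean)), 0.08)
  expect_lt(max(abs(cov(draws) - cond_cov)), 0.1 * max(abs(cond_cov)))
})

test_that("the chain is seed-reproducible and thinning retains the right draws", {
  obs <- simulate_lakes(sim_config(n_sites = 20, extent = c(100, 100),
                                   repeat_fraction = 0.5, mean_revisits = 4),
                        seed = 5)
  frame <- build_model_frame(obs$data)
  ctl <- mcmc_control(n_iter = 120, n_burn = 60, n_thin = 4, seed = 14)
  f1 <- fit_svc(frame, control = ctl)
  f2 <- fit_svc(frame, control = ctl)
  expect_identical(f1$samples, f2$samples)
  expect_equal(length(f1$samples$tau2), 15)

  single <- fit_svc(frame, control = mcmc_control(n_iter = 61, n_burn = 60,
                                                  n_thin = 1, seed = 2))
  expect_equal(length(single$samples$tau2), 1)
})

test_that("zero proposal scales freeze theta with acceptance one by convention", {
  obs <- simulate_lakes(sim_config(n_sites = 15, extent = c(80, 80),
                                   repeat_fraction = 0.5, mean_revisits = 3),
                        seed = 6)
  frame <- build_model_frame(obs$data)
  fit <- fit_svc(frame, control = mcmc_control(
    n_iter = 80, n_burn = 40, n_thin = 1, seed = 3,
    scale_phi = 0, scale_A = 0, adapt = FALSE
  ))
  expect_true(all(fit$acceptance == 1))
  expect_equal(var(fit$samples$phis[, 1]), 0)
  expect_equal(var(fit$samples$A_elements[, 1]), 0)
})

test_that("non-spatial posterior means match the conjugate closed form", {
  set.seed(9)
  obs <- simulate_lakes(sim_config(n_sites = 120, repeat_fraction = 0,
                                   A_true = matrix(0, 3, 3), tau2_true = 0.3),
                        seed = 12)
  frame <- build_model_frame(obs$data)
  fit <- fit_nonspatial(frame, control = mcmc_control(
    n_iter = 3000, n_burn = 500, n_thin = 1, seed = 8
  ))
  Z <- frame$design_svc
  ols <- unname(lm.fit(Z, frame$response)$coefficients)
  post_mean <- colMeans(fit$samples$beta_mu)
  mc_se <- apply(fit$samples$beta_mu, 2, sd) / sqrt(2500 / 4)
  expect_true(all(abs(post_mean - ols) < 4 * pmax(mc_se, 1e-4)))

  # exact-fit special case: response linear in TP with slope 1.06
  lin <- tiny_obs(8, lakes = 8)
  lin$chl <- 10^(0.2 + 1.06 * log10(lin$tp))
  lf <- build_model_frame(lin)
  lfit <- fit_nonspatial(lf, control = mcmc_control(n_iter = 2000, n_burn = 500,
                                                    n_thin = 1, seed = 4))
  expect_equal(mean(lfit$samples$beta_mu[, "log_tp"]), 1.06, tolerance = 0.02)
})

test_that("fitting with shuffled coordinates degrades the fit", {
  sh <- shared_small_fit()
  frame <- sh$frame
  set.seed(55)
  perm <- sample(nrow(frame$sites))
  shuffled <- frame
  shuffled$sites$x <- frame$sites$x[perm]
  shuffled$sites$y <- frame$sites$y[perm]
  refit <- fit_svc(shuffled, control = mcmc_control(
    n_iter = 700, n_burn = 350, n_thin = 2, seed = 78
  ))
  expect_gt(mean(sh$fit$samples$log_lik), mean(refit$samples$log_lik))
})

test_that("collinear designs fail with an informative error", {
  obs <- tiny_obs(8, lakes = 4)
  obs$color <- obs$tp  # log columns collinear
  frame <- build_model_frame(obs)
  expect_error(fit_nonspatial(frame), "[Ss]ingular|collinear")
})
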