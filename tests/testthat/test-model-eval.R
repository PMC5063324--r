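test_that("Gaussian CRPS matches numerical integration of the Brier integrand", {
  crps_numeric <- function(y, mu, sd) {
    stats::integrate(function(t) {
      (stats::pnorm(t, mu, sd) - as.numeric(t >= y))^2
    }, -Inf, Inf, rel.tol = 1e-10)$value
  }
  for (z in c(-2, -0.7, 0, 0.4, 1.8)) {
    for (sd in c(0.3, 1, 2.5)) {
      y <- z * sd
      expect_equal(crps_gaussian(y, 0, sd), crps_numeric(y, 0, sd),
                   tolerance = 1e-6)
    }
  }
  expect_equal(crps_gaussian(0, 0, 1), 0.23369, tolerance = 1e-4)
  # linear scaling in sigma at fixed standardized distance
  expect_equal(crps_gaussian(3 * 1.4, 0, 3), 3 * crps_gaussian(1.4, 0, 1))
  expect_error(crps_gaussian(0, 0, -1), "sd")
})

test_that("sample-based CRPS agrees with the closed form for Gaussian draws", {
  set.seed(17)
  draws <- rnorm(50000, mean = 1.2, sd = 0.8)
  for (y in c(0.5, 1.2, 3)) {
    expect_equal(crps_sample(y, draws), crps_gaussian(y, 1.2, 0.8),
                 tolerance = 0.01)
  }
  # sorted-identity implementation vs the direct O(n^2) pairwise oracle
  small <- rnorm(300)
  y <- 0.3
  direct <- mean(abs(small - y)) -
    mean(abs(outer(small, small, `-`))) / 2
  expect_equal(crps_sample(y, small), direct, tolerance = 1e-12)
})

test_that("DIC components follow their definitions", {
  obs <- simulate_lakes(sim_config(n_sites = 15, extent = c(50, 50),
                                   repeat_fraction = 0.5, mean_revisits = 3),
                        seed = 44)
  frame <- build_model_frame(obs$data)

  # point-mass posterior: one retained draw gives pD = 0
  fit1 <- fit_nonspatial(frame, control = mcmc_control(n_iter = 301,
                                                       n_burn = 300,
                                                       n_thin = 1, seed = 1))
  d1 <- compute_dic(fit1, frame)
  expect_equal(d1$pD, 0, tolerance = 1e-10)
  expect_equal(d1$DIC, d1$D_bar)
  expect_equal(d1$D_bar, -2 * fit1$samples$log_lik[1])

  # hand-computed oracle on a 3-row frame with a faked two-draw posterior
  f3 <- build_model_frame(tiny_obs(3, lakes = 3))
  fake <- structure(list(
    samples = list(
      beta_mu = rbind(c(0.1, 0.8, -0.1), c(0.3, 0.6, 0.1)),
      beta_fixed = matrix(0, 2, 0),
      tau2 = c(0.5, 0.9),
      log_lik = c(NA, NA)
    ),
    spatial = FALSE, svc_terms = colnames(f3$design_svc),
    fixed_terms = character(0), n_obs = 3
  ), class = "svc_fit")
  dev_draw <- function(b, t2) {
    mu <- drop(f3$design_svc %*% b)
    -2 * sum(dnorm(f3$response, mu, sqrt(t2), log = TRUE))
  }
  d_bar <- mean(c(dev_draw(c(0.1, 0.8, -0.1), 0.5),
                  dev_draw(c(0.3, 0.6, 0.1), 0.9)))
  d_hat <- dev_draw(c(0.2, 0.7, 0), 0.7)
  out <- compute_dic(fake, f3)
  expect_equal(out$D_bar, d_bar, tolerance = 1e-10)
  expect_equal(out$D_hat, d_hat, tolerance = 1e-10)
  expect_equal(out$pD, d_bar - d_hat, tolerance = 1e-10)
  expect_equal(out$DIC, d_bar + out$pD, tolerance = 1e-10)
})

test_that("effective parameter count is near 4 for a vague-prior regression", {
  set.seed(23)
  obs <- simulate_lakes(sim_config(n_sites = 2000, repeat_fraction = 0,
                                   A_true = matrix(0, 3, 3), tau2_true = 0.5),
                        seed = 61)
  frame <- build_model_frame(obs$data)
  fit <- fit_nonspatial(frame, control = mcmc_control(n_iter = 3500,
                                                      n_burn = 500,
                                                      n_thin = 1, seed = 7))
  out <- compute_dic(fit, frame)
  # three coefficients plus the variance
  expect_equal(out$pD, 4, tolerance = 0.5)
})

test_that("holdout scores match hand computation on a tabulated fixture", {
  # 4 observations, 200 tabulated draws each
  set.seed(99)
  obs_y <- c(0, 1, -0.5, 2)
  pred <- sapply(c(0, 1.2, -0.4, -1), function(mu) rnorm(200, mu, 0.5))
  scores <- score_holdout(pred, obs_y)
  means <- colMeans(pred)
  expect_equal(scores$rmspe, sqrt(mean((means - obs_y)^2)))
  qs <- apply(pred, 2, quantile, probs = c(0.025, 0.975), names = FALSE)
  expect_equal(scores$pci, 100 * mean(obs_y >= qs[1, ] & obs_y <= qs[2, ]))
  expect_equal(scores$piw, mean(qs[2, ] - qs[1, ]))
  expect_equal(scores$crps,
               mean(sapply(1:4, function(i) crps_sample(obs_y[i], pred[, i]))))

  # degenerate perfect predictions
  perfect <- matrix(rep(obs_y, each = 150), nrow = 150)
  s2 <- suppressWarnings(score_holdout(perfect, obs_y))
  expect_equal(s2$rmspe, 0)
  expect_equal(s2$pci, 100)
  expect_equal(s2$piw, 0)
})

test_that("posterior prediction collapses onto fitted values as noise vanishes", {
  frame <- build_model_frame(tiny_obs(6, lakes = 3))
  m <- nrow(frame$sites)
  coeffs <- matrix(c(0.2, 0.1, -0.1, 0.8, 0.7, 0.9, 0, 0.1, -0.2), m, 3)
  v <- coeffs  # identity A, zero beta_mu makes v the coefficients
  n_draws <- 120
  fake <- structure(list(
    samples = list(
      beta_mu = matrix(0, n_draws, 3),
      beta_fixed = matrix(0, n_draws, 0),
      tau2 = rep(1e-20, n_draws),
      phis = matrix(0.05, n_draws, 3),
      A_elements = matrix(rep(c(1, 0, 0, 1, 0, 1), each = n_draws), n_draws),
      v = array(rep(v, each = n_draws), c(n_draws, m, 3)),
      site_coeffs = array(rep(coeffs, each = n_draws), c(n_draws, m, 3)),
      log_lik = rep(0, n_draws)
    ),
    spatial = TRUE, svc_terms = colnames(frame$design_svc),
    fixed_terms = character(0), sites = frame$sites, n_obs = 6
  ), class = "svc_fit")
  pred <- posterior_predict(fake, frame, seed = 1)
  fitted <- rowSums(frame$design_svc * coeffs[frame$site_index, ])
  expect_equal(colMeans(pred), fitted, tolerance = 1e-8)
  expect_lt(max(apply(pred, 2, sd)), 1e-8)
})

test_that("predictions at remote new sites revert to the domain-wide mean", {
  frame <- build_model_frame(tiny_obs(6, lakes = 3))
  m <- nrow(frame$sites)
  beta_mu <- c(-0.4, 0.7, 0)
  a_diag <- c(0.5, 0.3, 0.2)
  n_draws <- 400
  set.seed(2)
  fake <- structure(list(
    samples = list(
      beta_mu = matrix(beta_mu, n_draws, 3, byrow = TRUE),
      beta_fixed = matrix(0, n_draws, 0),
      tau2 = rep(1e-20, n_draws),
      phis = matrix(0.05, n_draws, 3),
      A_elements = matrix(rep(c(a_diag[1], 0, 0, a_diag[2], 0, a_diag[3]),
                              each = n_draws), n_draws),
      v = array(rnorm(n_draws * m * 3), c(n_draws, m, 3)),
      site_coeffs = array(0, c(n_draws, m, 3)),
      log_lik = rep(0, n_draws)
    ),
    spatial = TRUE, svc_terms = colnames(frame$design_svc),
    fixed_terms = character(0), sites = frame$sites, n_obs = 6
  ), class = "svc_fit")
  far <- tiny_obs(40, lakes = 1)
  far$lake_id <- "FARAWAY"
  far$x <- 1e6
  far$y <- 1e6
  far$tp <- 14
  far$color <- 14
  hold <- build_model_frame(far)
  pred <- posterior_predict(fake, hold, seed = 3)
  xs <- hold$design_svc[1, ]
  expect_equal(mean(pred), sum(xs * beta_mu), tolerance = 0.1)
  # full marginal variance of the kriged coefficients
  expect_equal(var(as.vector(pred[, 1])), sum((xs * a_diag)^2),
               tolerance = 0.25)
})

test_that("predictive coverage is calibrated on self-simulated data", {
  sh <- shared_small_fit()
  sp <- split_holdout(sh$frame, fraction = 0.25, seed = 10)
  refit <- fit_svc(sp$train, control = mcmc_control(
    n_iter = 700, n_burn = 350, n_thin = 2, seed = 5
  ))
  pred <- posterior_predict(refit, sp$holdout, seed = 6)
  sc <- score_holdout(pred, sp$holdout)
  expect_gt(sc$pci, 85)
  expect_lte(sc$pci, 100)
  expect_gt(sc$rmspe, 0)
})
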