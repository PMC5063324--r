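#' Configuration for the synthetic lake-data generator
#'
#' Defaults emulate the structure of the north-temperate lake dataset the
#' model targets: ~840 lakes spread over a few hundred km (median
#' nearest-neighbour spacing ~6 km), right-skewed covariates matched by
#' median and spread to the study's summary table (TP and color medians
#' 14, maximum depth median 9.2 m, lake area median 55 ha, CA:LK median 10),
#' a drainage:isolated mix of roughly 72:28, a minority (~27%) of lakes with
#' many repeat observations (about 30 on average), and coefficient fields
#' whose true generating values are the fitted model's headline posterior
#' estimates: domain means (-0.36, 0.698, -0.02), residual variance 0.63,
#' and effective spatial ranges of about 33, 26 and 216 km for the
#' intercept, TP and color processes.
#'
#' @param n_sites Number of lakes. Default 838.
#' @param extent `c(width_km, height_km)` of the rectangular study region.
#'   Default `c(340, 340)` (reproduces ~6 km median nearest-neighbour
#'   spacing at the default density).
#' @param phis True decay rates per km for the intercept, log TP and log
#'   color coefficient processes. Defaults give effective ranges
#'   32.56 / 26.32 / 216.05 km.
#' @param A_true Lower-triangular 3 x 3 coregionalization matrix; its rows
#'   mix the latent processes into the coefficient fields, so `A_true %*%
#'   t(A_true)` is the between-coefficient covariance at distance zero. Set
#'   to a zero matrix for constant (non-spatial) coefficients.
#' @param beta_mu_true True domain-wide mean coefficients (intercept,
#'   log10 TP slope, log10 color slope).
#' @param beta_fixed_true Named true fixed-covariate coefficients on the
#'   log10 response scale, any subset of `log_depth`, `log_calk`,
#'   `prop_agriculture`, `prop_wetland`, `drainage`.
#' @param tau2_true True residual variance of log10 chlorophyll.
#' @param covariates Named list of `c(meanlog10, sdlog10)` pairs for the
#'   log-normal lake-level covariates `tp`, `color`, `depth`, `lake_area`,
#'   `calk`.
#' @param within_sd Log10-scale standard deviation of the per-observation
#'   redraw of TP and color around their lake-level values.
#' @param drainage_prob Probability a lake is a drainage (vs isolated) lake.
#' @param repeat_fraction Fraction of lakes receiving repeat observations.
#' @param mean_revisits Poisson mean of the number of extra observations for
#'   a revisited lake.
#' @param min_separation Minimum distance (km) enforced between sites by
#'   thinning-with-retry (0 disables).
#' @param years Calendar years sampled for observation dates.
#'
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(
    n_sites = 838,
    extent = c(340, 340),
    phis = decay_for_range(c(32.56, 26.32, 216.05)),
    A_true = rbind(
      c(0.30, 0.00, 0.00),
      c(0.05, 0.20, 0.00),
      c(-0.03, 0.02, 0.15)
    ),
    beta_mu_true = c(-0.36, 0.698, -0.02),
    beta_fixed_true = c(
      log_depth = -0.13, log_calk = 0.02, prop_agriculture = 0.45,
      prop_wetland = 0.16, drainage = 0.21
    ),
    tau2_true = 0.63,
    covariates = list(
      tp = c(log10(14), 0.41),
      color = c(log10(14), 0.37),
      depth = c(log10(9.2), 0.29),
      lake_area = c(log10(55.49), 0.60),
      calk = c(log10(10.06), 0.70)
    ),
    within_sd = 0.15,
    drainage_prob = 0.72,
    repeat_fraction = 0.27,
    mean_revisits = 29,
    min_separation = 0,
    years = 1986:2013) {
  stopifnot(n_sites >= 1, length(extent) == 2, all(extent > 0),
            length(phis) == 3, all(phis > 0), tau2_true >= 0,
            nrow(A_true) == 3, ncol(A_true) == 3,
            length(beta_mu_true) == 3)
  structure(
    list(
      n_sites = as.integer(n_sites), extent = extent, phis = phis,
      A_true = A_true, beta_mu_true = beta_mu_true,
      beta_fixed_true = beta_fixed_true, tau2_true = tau2_true,
      covariates = covariates, within_sd = within_sd,
      drainage_prob = drainage_prob, repeat_fraction = repeat_fraction,
      mean_revisits = mean_revisits, min_separation = min_separation,
      years = years
    ),
    class = "sim_config"
  )
}

#' Scatter synthetic lake sites over the study extent
#'
#' Uniform random locations in the extent rectangle, with optional
#' minimum-separation thinning (a rejected site is redrawn up to 100 times
#' before the generator gives up).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed.
#' @return A tibble with `lake_id`, `x`, `y` (km).
#' @export
simulate_sites <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  m <- config$n_sites
  xs <- numeric(m)
  ys <- numeric(m)
  for (i in seq_len(m)) {
    for (try in seq_len(100)) {
      cand <- stats::runif(2) * config$extent
      ok <- config$min_separation <= 0 || i == 1 ||
        min(sqrt((xs[seq_len(i - 1)] - cand[1])^2 +
                   (ys[seq_len(i - 1)] - cand[2])^2)) >= config$min_separation
      if (ok) break
      if (try == 100) {
        abort("Could not satisfy `min_separation` after 100 retries.")
      }
    }
    xs[i] <- cand[1]
    ys[i] <- cand[2]
  }
  tibble(
    lake_id = sprintf("L%04d", seq_len(m)),
    x = xs, y = ys
  )
}

#' Simulate a lake observation dataset from the SVC model
#'
#' Draws site-level coefficient fields from the multivariate GP prior (via
#' [sample_mvgp()]), lake-level covariates from right-skewed log-normal /
#' beta distributions, repeat observations for a random minority of lakes
#' (TP and color redrawn per visit around the lake-level value, coefficients
#' fixed), assembles the response on the log10 scale with `N(0, tau2_true)`
#' noise, and back-transforms chlorophyll to reporting units (ug/L).
#'
#' @param config A [sim_config()].
#' @param seed Optional integer seed; identical seed gives an identical
#'   dataset.
#' @return A list with `data` (the observation tibble, in the same dialect
#'   [apply_filters()] and [build_model_frame()] read) and `truth` (every
#'   generating parameter: the site table, the `n_sites x 3` coefficient
#'   field, the per-row noiseless linear predictor `mu`, and the config).
#' @export
simulate_lakes <- function(config = sim_config(), seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  sites <- simulate_sites(config)
  m <- config$n_sites
  q <- 3

  if (all(config$A_true == 0)) {
    coef_field <- matrix(config$beta_mu_true, m, q, byrow = TRUE)
  } else {
    params <- lmc_params(config$A_true, config$phis)
    draw <- sample_mvgp(sites, params, mean = config$beta_mu_true)
    coef_field <- matrix(draw[1, ], m, q)
  }

  # lake-level covariates
  cv <- config$covariates
  lake_log_tp <- stats::rnorm(m, cv$tp[1], cv$tp[2])
  lake_log_color <- stats::rnorm(m, cv$color[1], cv$color[2])
  max_depth <- 10^stats::rnorm(m, cv$depth[1], cv$depth[2])
  lake_area <- pmin(pmax(10^stats::rnorm(m, cv$lake_area[1], cv$lake_area[2]),
                         4.3), 9000)
  calk <- 10^stats::rnorm(m, cv$calk[1], cv$calk[2])
  catchment_area <- calk * lake_area
  prop_agriculture <- stats::rbeta(m, 0.5, 2.45)
  prop_wetland <- stats::rbeta(m, 0.4, 3.6)
  prop_urban <- stats::rbeta(m, 0.4, 3.6)
  prop_forest <- stats::rbeta(m, 0.4, 3.6)
  connectivity <- ifelse(stats::runif(m) < config$drainage_prob,
                         "drainage", "isolated")

  # visit structure: a minority of lakes is revisited many times
  revisited <- stats::runif(m) < config$repeat_fraction
  n_obs_lake <- 1L + ifelse(revisited, stats::rpois(m, config$mean_revisits), 0L)
  site_of_row <- rep(seq_len(m), n_obs_lake)
  n <- length(site_of_row)

  log_tp <- lake_log_tp[site_of_row] + stats::rnorm(n, 0, config$within_sd)
  log_color <- lake_log_color[site_of_row] + stats::rnorm(n, 0, config$within_sd)

  fixed_terms <- names(config$beta_fixed_true)
  fixed_vals <- cbind(
    log_depth = log10(max_depth),
    log_calk = log10(calk),
    prop_agriculture = prop_agriculture,
    prop_wetland = prop_wetland,
    drainage = as.numeric(connectivity == "drainage")
  )[site_of_row, fixed_terms, drop = FALSE]

  mu <- coef_field[site_of_row, 1] +
    coef_field[site_of_row, 2] * log_tp +
    coef_field[site_of_row, 3] * log_color
  if (length(fixed_terms) > 0) {
    mu <- mu + drop(fixed_vals %*% config$beta_fixed_true)
  }
  log_chl <- mu + stats::rnorm(n, 0, sqrt(config$tau2_true))

  # summer observation dates
  year <- sample(config$years, n, replace = TRUE)
  offset <- sample.int(93, n, replace = TRUE) - 1L
  date <- as.Date(sprintf("%d-06-15", year)) + offset

  data <- tibble(
    lake_id = sites$lake_id[site_of_row],
    x = sites$x[site_of_row],
    y = sites$y[site_of_row],
    date = date,
    chl = 10^log_chl,
    tp = 10^log_tp,
    color = 10^log_color,
    max_depth = max_depth[site_of_row],
    lake_area = lake_area[site_of_row],
    catchment_area = catchment_area[site_of_row],
    prop_agriculture = prop_agriculture[site_of_row],
    prop_wetland = prop_wetland[site_of_row],
    prop_urban = prop_urban[site_of_row],
    prop_forest = prop_forest[site_of_row],
    connectivity = connectivity[site_of_row]
  )
  truth <- list(
    sites = sites,
    coef_field = coef_field,
    mu = mu,
    beta_mu = config$beta_mu_true,
    beta_fixed = config$beta_fixed_true,
    tau2 = config$tau2_true,
    phis = config$phis,
    A = config$A_true,
    config = config
  )
  list(data = data, truth = truth)
}

#' Small filter-rule fixture with an answer key
#'
#' A ~20-row observation table embedding known violations of each inclusion
#' rule: two lake-area violations (one under, one over), two out-of-season
#' dates, two incomplete chlorophyll/TP/color triplets, and one missing
#' maximum depth. The column `expected_rule` names the first rule each row
#' fails (`NA` for compliant rows); the attribute `"expected_counts"` totals
#' them in rule order. Changing the seed changes the values but not the
#' violation pattern.
#'
#' @param seed Optional integer seed.
#' @param n_clean Number of fully compliant rows. Default 13.
#' @return A tibble in the [apply_filters()] dialect.
#' @export
simulate_filter_fixture <- function(seed = NULL, n_clean = 13) {
  if (!is.null(seed)) set.seed(seed)
  n_bad <- 7
  n <- n_clean + n_bad
  base <- tibble(
    lake_id = sprintf("F%03d", seq_len(n)),
    x = stats::runif(n, 0, 100),
    y = stats::runif(n, 0, 100),
    date = as.Date("2006-07-01") + sample.int(60, n, replace = TRUE),
    chl = 10^stats::rnorm(n, log10(4.5), 0.4),
    tp = 10^stats::rnorm(n, log10(14), 0.4),
    color = 10^stats::rnorm(n, log10(14), 0.35),
    max_depth = 10^stats::rnorm(n, log10(9.2), 0.3),
    lake_area = stats::runif(n, 10, 5000),
    catchment_area = stats::runif(n, 100, 20000),
    prop_agriculture = stats::runif(n, 0, 0.5),
    prop_wetland = stats::runif(n, 0, 0.4),
    prop_urban = stats::runif(n, 0, 0.3),
    prop_forest = stats::runif(n, 0, 0.5),
    connectivity = sample(c("drainage", "isolated"), n, replace = TRUE),
    expected_rule = NA_character_
  )
  bad <- n_clean + seq_len(n_bad)
  base$lake_area[bad[1]] <- 2.5
  base$lake_area[bad[2]] <- 15000
  base$expected_rule[bad[1:2]] <- "area"
  base$date[bad[3]] <- as.Date("2006-05-01")
  base$date[bad[4]] <- as.Date("2006-10-20")
  base$expected_rule[bad[3:4]] <- "season"
  base$color[bad[5]] <- NA
  base$tp[bad[6]] <- NA
  base$expected_rule[bad[5:6]] <- "triplet"
  base$max_depth[bad[7]] <- NA
  base$expected_rule[bad[7]] <- "depth"
  out <- base[sample.int(n), ]
  attr(out, "expected_counts") <- tibble(
    rule = c("area", "season", "triplet", "depth"),
    n_dropped = c(2L, 2L, 2L, 1L)
  )
  out
}
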