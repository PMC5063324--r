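# Shared fixtures, built in code at test time.

# A minimal compliant observation table with explicit values.
tiny_obs <- function(n = 6, lakes = 3) {
  tibble::tibble(
    lake_id = sprintf("T%02d", rep(seq_len(lakes), length.out = n)),
    x = rep(seq(0, 50, length.out = lakes), length.out = n),
    y = rep(seq(0, 30, length.out = lakes), length.out = n),
    date = as.Date("2006-07-10") + seq_len(n),
    chl = seq(2, 12, length.out = n),
    tp = seq(8, 30, length.out = n),
    color = seq(5, 40, length.out = n),
    max_depth = rep(9, n),
    lake_area = rep(50, n),
    catchment_area = rep(500, n),
    prop_agriculture = rep(0.2, n),
    prop_wetland = rep(0.1, n),
    prop_urban = rep(0.05, n),
    prop_forest = rep(0.3, n),
    connectivity = rep(c("drainage", "isolated"), length.out = n)
  )
}

# One moderate SVC fit shared across post-analysis tests (computed lazily).
.fit_cache <- new.env(parent = emptyenv())
shared_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    obs <- simulate_lakes(
      sim_config(n_sites = 50, extent = c(200, 200),
                 repeat_fraction = 0.4, mean_revisits = 10),
      seed = 77
    )
    frame <- build_model_frame(obs$data)
    fit <- fit_svc(frame, control = mcmc_control(
      n_iter = 700, n_burn = 350, n_thin = 2, seed = 78
    ))
    .fit_cache$obs <- obs
    .fit_cache$frame <- frame
    .fit_cache$fit <- fit
  }
  list(obs = .fit_cache$obs, frame = .fit_cache$frame, fit = .fit_cache$fit)
}
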