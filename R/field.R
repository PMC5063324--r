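#' Per-lake posterior coefficient summaries
#'
#' Summarizes the site-level coefficient chains of a spatial fit into one
#' row per lake and SVC term: posterior mean, sd, central credible bounds,
#' and a significance class — `"positive"` if the lower bound exceeds zero,
#' `"negative"` if the upper bound is below zero, `"null"` otherwise
#' (bounds touching zero are not excluded).
#'
#' @param fit A spatial [fit_svc()] object.
#' @param conf_level Credible mass of the interval. Default 0.95.
#' @return A tibble of class `"svc_field"` with columns `lake_id`, `x`, `y`,
#'   `term`, `estimate`, `std.error`, `conf.low`, `conf.high`,
#'   `significance`.
#' @export
coefficient_field <- function(fit, conf_level = 0.95) {
  stopifnot(inherits(fit, "svc_fit"))
  if (!fit$spatial) abort("Non-spatial fits have no site-level coefficients.")
  alpha <- (1 - conf_level) / 2
  q <- length(fit$svc_terms)
  m <- nrow(fit$sites)
  draws <- fit$samples$site_coeffs
  pieces <- purrr::map(seq_len(q), function(j) {
    d <- matrix(draws[, , j], ncol = m)
    qs <- apply(d, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE)
    tibble(
      lake_id = fit$sites$lake_id,
      x = fit$sites$x,
      y = fit$sites$y,
      term = fit$svc_terms[j],
      estimate = colMeans(d),
      std.error = apply(d, 2, stats::sd),
      conf.low = qs[1, ],
      conf.high = qs[2, ]
    )
  })
  out <- bind_rows(pieces) %>%
    mutate(significance = dplyr::case_when(
      .data$conf.low > 0 ~ "positive",
      .data$conf.high < 0 ~ "negative",
      TRUE ~ "null"
    ))
  class(out) <- c("svc_field", class(out))
  out
}

#' Count and summarize significance classes per coefficient
#'
#' @param field A [coefficient_field()] tibble (or any tibble with `term`,
#'   `estimate`, `conf.low`, `conf.high`).
#' @return A tibble with one row per (term, class): lake count `n` and the
#'   mean and sd of the posterior-mean coefficients in that class; classes
#'   with no lakes appear with `n = 0`.
#' @export
classify_significance <- function(field) {
  if (!"significance" %in% names(field)) {
    field <- field %>%
      mutate(significance = dplyr::case_when(
        .data$conf.low > 0 ~ "positive",
        .data$conf.high < 0 ~ "negative",
        TRUE ~ "null"
      ))
  }
  field %>%
    as_tibble() %>%
    mutate(significance = factor(.data$significance,
                                 levels = c("negative", "null", "positive"))) %>%
    group_by(.data$term, .data$significance, .drop = FALSE) %>%
    summarise(
      n = dplyr::n(),
      mean = if (dplyr::n() > 0) mean(.data$estimate) else NA_real_,
      sd = stats::sd(.data$estimate),
      .groups = "drop"
    )
}

#' Natural-scale effect of a log10-log10 slope
#'
#' A slope `b` on the log10-log10 scale is the exponent of the power law
#' `CHL = c * X^b`; its derivative at a reference point is
#' `b * chl / ref_value` — the change in chlorophyll (ug/L) per unit change
#' in the predictor, evaluated at reference chlorophyll `chl` and predictor
#' level `ref_value`.
#'
#' @param slope Log10-log10 regression coefficient(s).
#' @param chl Reference chlorophyll (ug/L), positive.
#' @param ref_value Reference predictor value (its own units), positive.
#' @return Effect in ug/L chlorophyll per predictor unit.
#' @examples
#' translate_effect(0.73, chl = 4.47, ref_value = 14) # ~0.233
#' @export
translate_effect <- function(slope, chl, ref_value) {
  if (any(chl <= 0) || any(ref_value <= 0)) {
    abort("`chl` and `ref_value` must be positive.")
  }
  slope * chl / ref_value
}

#' Per-lake natural-scale effects of a spatially-varying slope
#'
#' Combines a coefficient field with observed data: each lake's posterior
#' mean slope is translated at that lake's median observed chlorophyll and
#' predictor level.
#'
#' @param field A [coefficient_field()] tibble.
#' @param data The observation tibble the model was fitted to.
#' @param term SVC term to translate, default `"log_tp"`.
#' @param predictor Observation column holding the predictor in natural
#'   units, default `"tp"`.
#' @return A tibble with `lake_id`, `slope`, `chl_ref`, `predictor_ref`,
#'   `effect` (ug/L chlorophyll per predictor unit).
#' @export
translate_effects <- function(field, data, term = "log_tp", predictor = "tp") {
  refs <- data %>%
    as_tibble() %>%
    group_by(.data$lake_id) %>%
    summarise(
      chl_ref = stats::median(.data$chl),
      predictor_ref = stats::median(.data[[predictor]]),
      .groups = "drop"
    )
  field %>%
    as_tibble() %>%
    filter(.data$term == !!term) %>%
    select("lake_id", slope = "estimate") %>%
    dplyr::inner_join(refs, by = "lake_id") %>%
    mutate(effect = translate_effect(.data$slope, .data$chl_ref,
                                     .data$predictor_ref))
}

#' Inverse-distance-weighted coefficient surface
#'
#' Interpolates the posterior mean of one SVC term from the lake locations
#' onto a regular grid covering their bounding box. Weights are
#' `1 / distance^power`; a grid node coinciding with a lake takes that
#' lake's value exactly.
#'
#' @param field A [coefficient_field()] tibble.
#' @param term Which SVC term to interpolate.
#' @param cell_km Grid cell size in km. Default 5.
#' @param power IDW power. Default 2.
#' @return A tibble of class `"svc_surface"` with `x`, `y`, `value` and
#'   attributes `term` and `cell_km`. Plot with [autoplot()].
#' @export
interpolate_surface <- function(field, term, cell_km = 5, power = 2) {
  f <- dplyr::filter(as_tibble(field), .data$term == !!term)
  if (nrow(f) < 3) abort("Need at least 3 lakes to interpolate a surface.")
  check_number(cell_km, "cell_km", lower = 0, strict_lower = TRUE)
  gx <- seq(min(f$x), max(f$x), by = cell_km)
  gy <- seq(min(f$y), max(f$y), by = cell_km)
  if (length(gx) < 2 || length(gy) < 2) abort("Degenerate grid; reduce `cell_km`.")
  grid <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  d2 <- outer(grid$x, f$x, `-`)^2 + outer(grid$y, f$y, `-`)^2
  d <- sqrt(d2)
  w <- 1 / d^power
  exact <- d < 1e-9
  vals <- as.vector((w %*% f$estimate) / rowSums(w))
  hit <- which(rowSums(exact) > 0)
  for (i in hit) {
    vals[i] <- f$estimate[which(exact[i, ])[1]]
  }
  out <- tibble(x = grid$x, y = grid$y, value = vals)
  attr(out, "term") <- term
  attr(out, "cell_km") <- cell_km
  class(out) <- c("svc_surface", class(out))
  out
}

#' Pearson correlations between coefficient fields and lake covariates
#'
#' Correlates each SVC term's per-lake posterior mean with lake and
#' catchment covariates (numeric observation columns aggregated to one value
#' per lake by the median). Two-sided p-values are reported unadjusted for
#' multiplicity.
#'
#' @param field A [coefficient_field()] tibble.
#' @param data Observation tibble carrying the covariates and `lake_id`.
#' @param covariates Character vector of covariate column names.
#' @param alpha Significance level for the `significant` flag. Default 0.05.
#' @return A tibble with `term`, `covariate`, `estimate` (r), `p.value`,
#'   `significant`, `n`.
#' @export
correlate_with_covariates <- function(field, data, covariates, alpha = 0.05) {
  lake_table <- data %>%
    as_tibble() %>%
    group_by(.data$lake_id) %>%
    summarise(dplyr::across(dplyr::all_of(covariates),
                            ~ stats::median(.x, na.rm = TRUE)),
              .groups = "drop")
  terms <- unique(field$term)
  rows <- purrr::map(terms, function(tm) {
    coefs <- field %>%
      as_tibble() %>%
      filter(.data$term == tm) %>%
      dplyr::inner_join(lake_table, by = "lake_id")
    purrr::map(covariates, function(cv) {
      x <- coefs[[cv]]
      if (stats::sd(x, na.rm = TRUE) == 0) {
        abort(sprintf("Covariate `%s` has zero variance.", cv))
      }
      ct <- stats::cor.test(coefs$estimate, x, method = "pearson")
      tibble(term = tm, covariate = cv,
             estimate = unname(ct$estimate), p.value = ct$p.value,
             significant = ct$p.value < alpha, n = nrow(coefs))
    }) %>% bind_rows()
  })
  message("Pearson p-values are reported without multiplicity adjustment.")
  bind_rows(rows)
}

#' Welch two-sample contrasts of coefficient fields by connectivity type
#'
#' For each SVC term, compares per-lake posterior mean coefficients between
#' drainage and isolated lakes with an unequal-variance (Welch) two-sample
#' t-test.
#'
#' @param field A [coefficient_field()] tibble.
#' @param data Observation tibble with `lake_id` and `connectivity`.
#' @return A tibble with `term`, `statistic` (t), `df`
#'   (Welch-Satterthwaite), `p.value`, `mean_drainage`, `mean_isolated`.
#' @export
contrast_by_connectivity <- function(field, data) {
  types <- data %>%
    as_tibble() %>%
    distinct(.data$lake_id, .data$connectivity)
  joined <- field %>%
    as_tibble() %>%
    dplyr::inner_join(types, by = "lake_id")
  terms <- unique(joined$term)
  purrr::map(terms, function(tm) {
    d <- filter(joined, .data$term == tm)
    a <- d$estimate[d$connectivity == "drainage"]
    b <- d$estimate[d$connectivity == "isolated"]
    if (length(a) < 2 || length(b) < 2) {
      abort("Each connectivity group needs at least 2 lakes.")
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    tibble(
      term = tm,
      statistic = unname(tt$statistic),
      df = unname(tt$parameter),
      p.value = tt$p.value,
      mean_drainage = mean(a),
      mean_isolated = mean(b)
    )
  }) %>% bind_rows()
}
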