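#' Assemble the regression frame for SVC model fitting
#'
#' Builds the response and design matrices of the chlorophyll model
#' `y_t(s) = x~_t(s)' b~(s) + x_t(s)' b + e_t(s)`: the response is
#' log10 chlorophyll, the spatially-varying design is
#' `[1, log10 TP, log10 color]`, and the fixed (space-invariant) design is a
#' configurable subset of log10 maximum depth, log10 catchment:lake area
#' ratio, catchment agriculture and wetland proportions, and a drainage
#' connectivity dummy (1 = drainage, 0 = isolated). Repeated observations of
#' one lake share a single site; sites are the unique lakes with one planar
#' coordinate each.
#'
#' @param data Filtered observation tibble with planar `x`, `y` (km).
#' @param fixed_terms Character vector choosing the fixed covariates, any of
#'   `"log_depth"`, `"log_calk"`, `"prop_agriculture"`, `"prop_wetland"`,
#'   `"drainage"`. Use `character(0)` (default) for the nutrient-color-only
#'   models.
#' @param jitter_km Distinct lakes with exactly coincident coordinates are
#'   jittered by this amount (km) so spatial covariance matrices stay
#'   nonsingular; a warning reports how many. Default 0.001.
#'
#' @return An object of class `"svc_frame"`: a list with `response`,
#'   `design_svc`, `design_fixed`, `sites` (tibble `lake_id`, `x`, `y`),
#'   `site_index` (row -> site), and the kept observation `data`.
#' @examples
#' obs <- simulate_lakes(sim_config(n_sites = 20, mean_revisits = 2), seed = 1)
#' frame <- build_model_frame(obs$data)
#' frame
#' @export
build_model_frame <- function(data, fixed_terms = character(0),
                              jitter_km = 0.001) {
  data <- as_tibble(data)
  allowed <- c(
    "log_depth", "log_calk", "prop_agriculture", "prop_wetland", "drainage"
  )
  bad <- setdiff(fixed_terms, allowed)
  if (length(bad) > 0) {
    abort(paste0("Unknown fixed term(s): ", paste(bad, collapse = ", ")))
  }
  needed <- c("lake_id", "x", "y", "chl", "tp", "color")
  miss <- setdiff(needed, names(data))
  if (length(miss) > 0) {
    abort(paste0("Missing column(s): ", paste(miss, collapse = ", ")))
  }
  log10_checked(data$chl, "chl", data$lake_id)
  log10_checked(data$tp, "tp", data$lake_id)
  log10_checked(data$color, "color", data$lake_id)

  response <- log10(data$chl)
  design_svc <- cbind(
    intercept = 1,
    log_tp = log10(data$tp),
    log_color = log10(data$color)
  )
  cols <- list()
  if ("log_depth" %in% fixed_terms) {
    cols$log_depth <- log10_checked(data$max_depth, "max_depth", data$lake_id)
  }
  if ("log_calk" %in% fixed_terms) {
    calk <- data$catchment_area / data$lake_area
    cols$log_calk <- log10_checked(calk, "catchment_area/lake_area", data$lake_id)
  }
  if ("prop_agriculture" %in% fixed_terms) cols$prop_agriculture <- data$prop_agriculture
  if ("prop_wetland" %in% fixed_terms) cols$prop_wetland <- data$prop_wetland
  if ("drainage" %in% fixed_terms) {
    cols$drainage <- as.numeric(data$connectivity == "drainage")
  }
  design_fixed <- if (length(cols) > 0) {
    do.call(cbind, cols)
  } else {
    matrix(0, nrow(data), 0)
  }
  if (anyNA(design_fixed)) {
    abort("Fixed covariates contain missing values after filtering.")
  }

  sites <- data %>%
    group_by(.data$lake_id) %>%
    slice(1) %>%
    ungroup() %>%
    select("lake_id", "x", "y") %>%
    arrange(.data$lake_id)
  sites <- jitter_coincident(sites, jitter_km)
  site_index <- match(data$lake_id, sites$lake_id)

  structure(
    list(
      response = response,
      design_svc = design_svc,
      design_fixed = design_fixed,
      sites = sites,
      site_index = site_index,
      data = data
    ),
    class = "svc_frame"
  )
}

log10_checked <- function(x, field, lake_id) {
  bad <- !is.na(x) & x <= 0
  if (any(bad)) {
    abort(sprintf(
      "Nonpositive `%s` cannot be log10-transformed (lake %s).",
      field, paste(utils::head(unique(lake_id[bad]), 3), collapse = ", ")
    ))
  }
  if (anyNA(x)) {
    abort(sprintf("Missing `%s` encountered after filtering.", field))
  }
  log10(x)
}

# Deterministically separate exactly coincident distinct lakes.
jitter_coincident <- function(sites, jitter_km) {
  key <- paste(sites$x, sites$y)
  dup <- duplicated(key)
  if (any(dup)) {
    warn(sprintf(
      "%d lake(s) share coordinates with another lake; jittered by %g km.",
      sum(dup), jitter_km
    ))
    idx <- which(dup)
    ang <- 2 * pi * seq_along(idx) / (length(idx) + 1)
    sites$x[idx] <- sites$x[idx] + jitter_km * cos(ang)
    sites$y[idx] <- sites$y[idx] + jitter_km * sin(ang)
  }
  sites
}

#' @export
print.svc_frame <- function(x, ...) {
  cat(sprintf(
    "<svc_frame> %d observations at %d lake sites\n",
    length(x$response), nrow(x$sites)
  ))
  cat(
    "  svc terms:  ", paste(colnames(x$design_svc), collapse = ", "), "\n",
    "  fixed terms:",
    if (ncol(x$design_fixed) > 0) {
      paste(colnames(x$design_fixed), collapse = ", ")
    } else {
      "(none)"
    },
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Partition a model frame into training and holdout sets
#'
#' Observations (not lakes) are assigned to the holdout set at random, so a
#' lake with repeated samples may contribute rows to both partitions. The
#' holdout size is `floor(fraction * n)`.
#'
#' @param frame An [build_model_frame()] result.
#' @param fraction Holdout fraction in (0, 1). Default 0.10.
#' @param seed Optional integer seed for a reproducible split.
#'
#' @return A list with `svc_frame` elements `train` and `holdout`.
#' @export
split_holdout <- function(frame, fraction = 0.10, seed = NULL) {
  stopifnot(inherits(frame, "svc_frame"))
  check_number(fraction, "fraction", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  n <- length(frame$response)
  if (n < 1) abort("Cannot split an empty frame.")
  n_hold <- floor(fraction * n)
  if (!is.null(seed)) set.seed(seed)
  hold_idx <- sort(sample.int(n, n_hold))
  list(
    train = subset_frame(frame, setdiff(seq_len(n), hold_idx)),
    holdout = subset_frame(frame, hold_idx)
  )
}

# Rebuild an svc_frame from a row subset (site list shrinks to the lakes
# present in the subset; coordinates keep any jitter already applied).
subset_frame <- function(frame, idx) {
  data <- frame$data[idx, , drop = FALSE]
  keep_sites <- frame$sites[frame$sites$lake_id %in% data$lake_id, , drop = FALSE]
  structure(
    list(
      response = frame$response[idx],
      design_svc = frame$design_svc[idx, , drop = FALSE],
      design_fixed = frame$design_fixed[idx, , drop = FALSE],
      sites = keep_sites,
      site_index = match(data$lake_id, keep_sites$lake_id),
      data = data
    ),
    class = "svc_frame"
  )
}

#' Nearest-neighbour distance summary for lake sites
#'
#' @param sites A data frame with `x`, `y` in km (for example the `sites`
#'   element of an `svc_frame`), or an `svc_frame`.
#' @return A one-row tibble with `median_km`, `min_km`, `max_km` of the
#'   per-site nearest-neighbour Euclidean distances.
#' @examples
#' nearest_neighbor_summary(tibble::tibble(x = c(0, 1, 3), y = 0))
#' @export
nearest_neighbor_summary <- function(sites) {
  if (inherits(sites, "svc_frame")) sites <- sites$sites
  if (nrow(sites) < 2) abort("Need at least 2 sites.")
  d <- as.matrix(stats::dist(cbind(sites$x, sites$y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  tibble(
    median_km = stats::median(nn),
    min_km = min(nn),
    max_km = max(nn)
  )
}
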