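#' Inclusion-rule configuration for lake observations
#'
#' The study population is lakes with surface area strictly between
#' `area_min` and `area_max` hectares, sampled in the summer index window
#' (inclusive on both end dates), with chlorophyll, total phosphorus and
#' water color all measured during the same sampling event, and with a known
#' maximum depth.
#'
#' @param area_min,area_max Open-interval lake-area bounds (ha). Defaults 4
#'   and 10000; boundary values are excluded.
#' @param season_start,season_end Month-day strings (`"MM-DD"`) delimiting the
#'   sampling window, inclusive. Defaults `"06-15"` and `"09-15"`.
#' @param require_triplet Require chlorophyll, TP and color all non-missing on
#'   the same row (same sampling event). Default `TRUE`.
#' @param require_depth Require non-missing maximum depth. Default `TRUE`.
#'
#' @return A list of class `"filter_config"`.
#' @examples
#' filter_config(area_min = 1)
#' @export
filter_config <- function(area_min = 4, area_max = 10000,
                          season_start = "06-15", season_end = "09-15",
                          require_triplet = TRUE, require_depth = TRUE) {
  check_number(area_min, "area_min", lower = 0)
  check_number(area_max, "area_max", lower = area_min, strict_lower = TRUE)
  if (season_start > season_end) {
    abort("Season window is empty (`season_start` after `season_end`).")
  }
  structure(
    list(
      area_min = area_min, area_max = area_max,
      season_start = season_start, season_end = season_end,
      require_triplet = isTRUE(require_triplet),
      require_depth = isTRUE(require_depth)
    ),
    class = "filter_config"
  )
}

#' Apply the study inclusion rules to an observation table
#'
#' Rules are applied in a fixed order — lake area, season window, same-event
#' completeness of the chlorophyll/TP/color triplet, maximum depth — and each
#' dropped row is attributed to the first rule it fails. The kept set itself
#' does not depend on rule order, only the attribution does.
#'
#' @param data Observation tibble with (at least) `lake_area`, `date`, `chl`,
#'   `tp`, `color`, `max_depth` columns.
#' @param config A [filter_config()].
#'
#' @return The kept rows as a tibble, with the drop log attached as attribute
#'   `"drop_log"` (retrieve with [filter_log()]): a tibble of per-rule dropped
#'   row counts, in application order.
#' @examples
#' fx <- simulate_filter_fixture(seed = 1)
#' kept <- apply_filters(fx, filter_config())
#' filter_log(kept)
#' @export
apply_filters <- function(data, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  data <- as_tibble(data)
  n <- nrow(data)
  fail_area <- !is.na(data$lake_area) &
    !(data$lake_area > config$area_min & data$lake_area < config$area_max)
  fail_area <- fail_area | is.na(data$lake_area)
  md <- month_day(as.Date(data$date))
  fail_season <- is.na(md) | md < config$season_start | md > config$season_end
  fail_triplet <- if (config$require_triplet) {
    is.na(data$chl) | is.na(data$tp) | is.na(data$color)
  } else {
    rep(FALSE, n)
  }
  fail_depth <- if (config$require_depth) {
    is.na(data$max_depth)
  } else {
    rep(FALSE, n)
  }
  first_fail <- rep(NA_character_, n)
  first_fail[fail_depth] <- "depth"
  first_fail[fail_triplet] <- "triplet"
  first_fail[fail_season] <- "season"
  first_fail[fail_area] <- "area"
  rules <- c("area", "season", "triplet", "depth")
  log <- tibble(
    rule = rules,
    n_dropped = unname(vapply(
      rules, function(r) sum(first_fail == r, na.rm = TRUE), integer(1)
    ))
  )
  kept <- data[is.na(first_fail), , drop = FALSE]
  attr(kept, "drop_log") <- log
  kept
}

#' Retrieve the drop log from a filtered observation table
#'
#' @param data The tibble returned by [apply_filters()].
#' @return A tibble with columns `rule` and `n_dropped`.
#' @export
filter_log <- function(data) {
  log <- attr(data, "drop_log")
  if (is.null(log)) abort("`data` carries no drop log; was it filtered?")
  log
}
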