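#' Project lake coordinates to a planar km system
#'
#' Adds planar coordinates `x`, `y` (kilometres) to a lake observation table.
#' The default method is an equidistant conic projection on a spherical earth,
#' centred on the bounding box of the data, with standard parallels at one
#' sixth and five sixths of the latitude range. Within a study extent of a few
#' hundred kilometres, pairwise Euclidean distances in the projected plane
#' approximate great-circle distances to well under one percent.
#'
#' @param data A data frame of lake observations. For `method = "eqdc"` it
#'   must carry `lon` and `lat` columns in decimal degrees; for
#'   `method = "none"` it must already carry planar `x`, `y` in km, which are
#'   passed through unchanged.
#' @param method `"eqdc"` (equidistant conic, the default) or `"none"`
#'   (coordinates already planar).
#' @param center Optional `c(lon, lat)` projection origin; defaults to the
#'   bounding-box centre of the data.
#' @param parallels Optional two standard parallels (degrees latitude);
#'   defaults to the 1/6 and 5/6 points of the latitude range.
#'
#' @return The input as a tibble with finite numeric `x` and `y` columns (km).
#' @examples
#' pts <- tibble::tibble(lake_id = c("a", "b"), lon = c(-89, -89), lat = c(44, 45))
#' project_coordinates(pts)
#' @export
project_coordinates <- function(data, method = c("eqdc", "none"),
                                center = NULL, parallels = NULL) {
  method <- match.arg(method)
  data <- as_tibble(data)
  if (method == "none") {
    if (!all(c("x", "y") %in% names(data))) {
      abort("`method = \"none\"` requires planar `x` and `y` columns (km).")
    }
    return(data)
  }
  if (!all(c("lon", "lat") %in% names(data))) {
    abort("`method = \"eqdc\"` requires `lon` and `lat` columns (degrees).")
  }
  lon <- data$lon
  lat <- data$lat
  bad <- !is.finite(lon) | !is.finite(lat) | abs(lat) > 90 | abs(lon) > 360
  if (any(bad)) {
    ids <- if ("lake_id" %in% names(data)) data$lake_id[bad] else which(bad)
    abort(paste0(
      "Coordinates outside projection validity for lake(s): ",
      paste(utils::head(unique(ids), 5), collapse = ", ")
    ))
  }
  if (is.null(center)) {
    center <- c(mean(range(lon)), mean(range(lat)))
  }
  if (is.null(parallels)) {
    r <- range(lat)
    parallels <- r[1] + c(1 / 6, 5 / 6) * diff(r)
  }
  xy <- eqdc_forward(lon, lat, center, parallels)
  data$x <- xy$x
  data$y <- xy$y
  if (any(!is.finite(data$x) | !is.finite(data$y))) {
    abort("Projection produced non-finite coordinates.")
  }
  data
}

# Equidistant conic forward projection, spherical earth (mean radius km).
eqdc_forward <- function(lon, lat, center, parallels, radius = 6371.0088) {
  d2r <- pi / 180
  lam <- lon * d2r
  phi <- lat * d2r
  lam0 <- center[1] * d2r
  phi0 <- center[2] * d2r
  phi1 <- parallels[1] * d2r
  phi2 <- parallels[2] * d2r
  n <- if (abs(phi1 - phi2) < 1e-12) {
    sin(phi1)
  } else {
    (cos(phi1) - cos(phi2)) / (phi2 - phi1)
  }
  if (abs(n) < 1e-12) {
    abort("Degenerate standard parallels (cone constant ~ 0); choose others.")
  }
  g <- cos(phi1) / n + phi1
  rho <- g - phi
  rho0 <- g - phi0
  theta <- n * (lam - lam0)
  list(
    x = radius * rho * sin(theta),
    y = radius * (rho0 - rho * cos(theta))
  )
}
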