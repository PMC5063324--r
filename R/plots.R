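#' Plot an interpolated coefficient surface
#'
#' @param object An [interpolate_surface()] result.
#' @param ... Unused.
#' @return A ggplot raster of the surface with equal coordinates.
#' @method autoplot svc_surface
#' @export
autoplot.svc_surface <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "x (km)", y = "y (km)", fill = attr(object, "term"),
      title = paste("Interpolated posterior mean:", attr(object, "term"))
    )
}

#' Map per-lake coefficients or their significance classes
#'
#' Point map of the lakes, faceted by SVC term, coloured either by the
#' posterior mean coefficient or by the significance class of its credible
#' interval (the style of a significance dot map).
#'
#' @param object A [coefficient_field()] tibble.
#' @param what `"estimate"` (default) or `"significance"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot svc_field
#' @export
autoplot.svc_field <- function(object, what = c("estimate", "significance"),
                               ...) {
  what <- match.arg(what)
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::facet_wrap(~term) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)")
  if (what == "estimate") {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$estimate), size = 1) +
      ggplot2::scale_colour_viridis_c()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$significance),
                            size = 1) +
      ggplot2::scale_colour_manual(
        values = c(negative = "#b2182b", null = "grey40",
                   positive = "#2166ac")
      )
  }
}

#' Trace plots for scalar chains of a fit
#'
#' @param fit An `svc_fit`.
#' @param pars Parameter names among the tidy terms (defaults to `tau2` and
#'   the SVC means).
#' @return A ggplot of retained-draw traces, one facet per parameter.
#' @export
plot_traces <- function(fit, pars = NULL) {
  stopifnot(inherits(fit, "svc_fit"))
  chains <- cbind(
    fit$samples$beta_mu, fit$samples$beta_fixed, tau2 = fit$samples$tau2,
    if (fit$spatial) fit$samples$phis else NULL
  )
  if (is.null(pars)) pars <- c(fit$svc_terms, "tau2")
  pars <- intersect(pars, colnames(chains))
  long <- as_tibble(chains[, pars, drop = FALSE]) %>%
    mutate(iteration = dplyr::row_number()) %>%
    tidyr::pivot_longer(-"iteration", names_to = "term")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "retained draw", y = NULL)
}
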