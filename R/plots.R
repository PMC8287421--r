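#' Plot methods for wcdelay results
#'
#' `autoplot()` methods give quick ggplot2 views of each result type:
#' excitatory traces for trajectories, spectra on the unit circle, Hopf
#' boundaries in the `(W_IE, W_E)` plane, orbit diagrams as peak maps,
#' MSF regions as filled rasters with the zero-level boundary, and
#' synchronization predictions as eigenvalues colored by their exponent.
#'
#' @param object A wcdelay result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name wcdelay-autoplot
NULL

unit_circle_df <- function(n = 361) {
  th <- seq(0, 2 * pi, length.out = n)
  data.frame(re = cos(th), im = sin(th))
}

#' @rdname wcdelay-autoplot
#' @export
autoplot.wc_trajectory <- function(object, ...) {
  tb <- as_tibble(object)
  Evars <- grep("^E", object$vars, value = TRUE)
  long <- tidyr::pivot_longer(tb[, c("t", Evars)], -"t",
                              names_to = "node", values_to = "E")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$E,
                                     colour = .data$node)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time", y = "excitatory activity") +
    ggplot2::theme_minimal()
}

#' @rdname wcdelay-autoplot
#' @export
autoplot.wc_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$re_scaled, .data$im_scaled)) +
    ggplot2::geom_path(data = unit_circle_df(),
                       ggplot2::aes(.data$re, .data$im),
                       linetype = 2, colour = "grey60",
                       inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$is_perron), size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re r", y = "Im r", shape = "Perron") +
    ggplot2::theme_minimal()
}

#' @rdname wcdelay-autoplot
#' @export
autoplot.wc_hopf_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$W_IE, .data$W_E_hopf,
                               colour = factor(.data$eps))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "W_IE", y = "W_E at Hopf", colour = "delay") +
    ggplot2::theme_minimal()
}

#' @rdname wcdelay-autoplot
#' @export
autoplot.wc_orbit_diagram <- function(object, ...) {
  tb <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$peak))
  ggplot2::ggplot(tb, ggplot2::aes(.data$W_E, .data$peak)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::labs(x = "W_E", y = "E peak values",
                  title = sprintf("delay = %g", attr(object, "eps"))) +
    ggplot2::theme_minimal()
}

#' @rdname wcdelay-autoplot
#' @export
autoplot.wc_msf <- function(object, ...) {
  tb <- tibble::as_tibble(object)
  bnd <- attr(object, "boundary")
  pl <- ggplot2::ggplot(tb, ggplot2::aes(.data$re, .data$im)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$lambda)) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::geom_path(data = unit_circle_df(),
                       ggplot2::aes(.data$re, .data$im),
                       linetype = 2, colour = "grey30",
                       inherit.aes = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re r", y = "Im r", fill = "lambda") +
    ggplot2::theme_minimal()
  for (b in bnd)
    pl <- pl + ggplot2::geom_path(data = b,
                                  ggplot2::aes(.data$re, .data$im),
                                  colour = "black", inherit.aes = FALSE)
  pl
}

#' @rdname wcdelay-autoplot
#' @export
autoplot.wc_sync_prediction <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$re_scaled, .data$im_scaled,
                               colour = .data$lambda,
                               shape = .data$role)) +
    ggplot2::geom_path(data = unit_circle_df(),
                       ggplot2::aes(.data$re, .data$im),
                       linetype = 2, colour = "grey60",
                       inherit.aes = FALSE) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_gradient2(low = "steelblue", mid = "grey80",
                                    high = "firebrick", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Re r", y = "Im r",
                  title = sprintf("verdict: %s", attr(object, "verdict"))) +
    ggplot2::theme_minimal()
}
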