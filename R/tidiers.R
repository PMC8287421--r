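#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tibble::as_tibble

#' Tidiers for wcdelay result objects
#'
#' `tidy()` returns the per-element table of a result (one row per
#' eigenvalue, grid point, cluster, ...); `glance()` returns a one-row
#' summary.
#'
#' @param x A wcdelay result object.
#' @param ... Unused.
#' @return A tibble.
#' @name wcdelay-tidiers
NULL

#' @rdname wcdelay-tidiers
#' @export
tidy.wc_equilibrium <- function(x, ...) {
  tibble::tibble(E = x$E, I = x$I, W_EI = x$W_EI)
}

#' @rdname wcdelay-tidiers
#' @export
tidy.wc_spectrum <- function(x, ...) tibble::as_tibble(x)

#' @rdname wcdelay-tidiers
#' @export
tidy.wc_lyap <- function(x, ...) {
  tibble::tibble(re_r_hat = Re(x$r_hat), im_r_hat = Im(x$r_hat),
                 W_E = x$W_E, eps = x$eps, m = x$m, lambda = x$lambda,
                 converged = x$converged, marginal = x$marginal,
                 t_avg_used = x$t_avg_used)
}

#' @rdname wcdelay-tidiers
#' @export
tidy.wc_sync_prediction <- function(x, ...) tibble::as_tibble(x)

#' @rdname wcdelay-tidiers
#' @export
glance.wc_sync_prediction <- function(x, ...) {
  trans <- x$lambda[x$role == "transverse"]
  tibble::tibble(verdict = attr(x, "verdict"),
                 W_E = attr(x, "W_E"), eps = attr(x, "eps"),
                 n_eigenvalues = nrow(x),
                 max_transverse_lambda = max(trans, -Inf),
                 perron_lambda = attr(x, "perron_lambda"))
}

#' @rdname wcdelay-tidiers
#' @export
tidy.wc_orbit_diagram <- function(x, ...) tibble::as_tibble(x)

#' @rdname wcdelay-tidiers
#' @export
glance.wc_orbit_diagram <- function(x, ...) {
  tb <- tibble::as_tibble(x)
  counts <- dplyr::distinct(dplyr::select(tb, "W_E", "n_clusters"))
  tibble::tibble(eps = attr(x, "eps"),
                 n_couplings = nrow(counts),
                 max_clusters = max(counts$n_clusters, 0L, na.rm = TRUE),
                 any_period_doubled = any(counts$n_clusters >= 2,
                                          na.rm = TRUE))
}

#' @rdname wcdelay-tidiers
#' @export
tidy.wc_msf <- function(x, ...) tibble::as_tibble(x)

#' @rdname wcdelay-tidiers
#' @export
glance.wc_msf <- function(x, ...) {
  tibble::tibble(W_E = attr(x, "W_E"), eps = attr(x, "eps"),
                 n_grid = nrow(x),
                 frac_stable = mean(x$lambda < 0, na.rm = TRUE),
                 n_boundary_curves = length(attr(x, "boundary")))
}

#' @rdname wcdelay-tidiers
#' @export
tidy.wc_threshold_scan <- function(x, ...) tibble::as_tibble(x)

#' @rdname wcdelay-tidiers
#' @export
glance.wc_threshold_scan <- function(x, ...) {
  tibble::tibble(topology = attr(x, "topology"),
                 smallest_desync_msf = attr(x, "smallest_desync_msf"),
                 smallest_desync_sim = attr(x, "smallest_desync_sim"),
                 smallest_desync_confirmed =
                   attr(x, "smallest_desync_confirmed"),
                 all_agree = all(x$agree))
}
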