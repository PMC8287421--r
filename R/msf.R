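#' Settings for Lyapunov-exponent estimation
#'
#' Controls the Benettin-style computation behind the Master Stability
#' Function: the synchronous node runs alone for `transient` time units
#' to reach its attractor, the variational system then runs for
#' `var_skip` units (renormalized but not yet accumulated) to align with
#' the leading direction, and log norm growth is accumulated over
#' `t_avg` units with renormalization every `renorm_dt`. The exponent is
#' declared converged when the running time-average moves by less than
#' `conv_tol` over the second half of the accumulation; with
#' `extend = TRUE` a non-converged estimate is recomputed with doubled
#' averaging time up to `max_avg`.
#'
#' @param step Integrator step (`NULL`: `min(0.01, eps / 4)`, also capped
#'   by chain stability at `2.5 * eps / m`).
#' @param transient Synchronous-node transient, time units.
#' @param var_skip Variational alignment time excluded from the average.
#' @param t_avg Accumulation time for the exponent.
#' @param renorm_dt Renormalization interval.
#' @param conv_tol Convergence tolerance on the running mean.
#' @param extend Double `t_avg` (up to `max_avg`) while unconverged.
#' @param max_avg Cap on the extended averaging time.
#' @return A list of class `wc_lyap_config`.
#' @export
lyap_config <- function(step = NULL, transient = 500, var_skip = 50,
                        t_avg = 2000, renorm_dt = 1, conv_tol = 1e-3,
                        extend = TRUE, max_avg = 8000) {
  structure(list(step = step, transient = transient, var_skip = var_skip,
                 t_avg = t_avg, renorm_dt = renorm_dt, conv_tol = conv_tol,
                 extend = extend, max_avg = max_avg),
            class = "wc_lyap_config")
}

lyap_step <- function(cfg, eps, m) {
  h <- if (is.null(cfg$step)) 0.01 else cfg$step
  if (eps > 0) h <- min(h, eps / 4, 2.5 * eps / m) # RK4 stability of the chain
  # keep the renormalization interval an integer number of steps
  n <- max(1L, round(cfg$renorm_dt / h))
  cfg$renorm_dt / n
}

lyap_node0 <- function(W_E, node) {
  eq <- equilibrium(W_E, node)
  c(eq$E + 0.01, eq$I, eq$W_EI)
}

#' Maximal Lyapunov exponent of the delayed variational system
#'
#' The Master Stability Function at a connectivity eigenvalue `r_hat`:
#' the synchronous single self-coupled node is co-integrated with the
#' variational system in the transverse direction associated with
#' `r_hat`, whose delayed term is replaced by an `m`-cell advection chain
#' (delay-line discretization), turning the linear DDE into ODEs to
#' which the classical Benettin renormalization applies. Negative values
#' mean perturbations in that eigendirection decay; the synchronous
#' solution of a network is stable when the exponent is negative at
#' every eigenvalue transverse to the synchronous (Perron) direction.
#'
#' `r_hat` is a raw eigenvalue of the weight matrix; callers working on
#' the scaled unit disk should multiply by `W_E` first (as
#' [msf_region()] does).
#'
#' @param r_hat Complex (or real) connectivity eigenvalue.
#' @param W_E Global coupling of the synchronous node.
#' @param eps Delay.
#' @param node A [node_params()] bundle.
#' @param m Number of chain cells (delay-line resolution).
#' @param cfg A [lyap_config()].
#' @return A list of class `wc_lyap`: `lambda` (the exponent),
#'   `converged`, `marginal` (`|lambda|` below the convergence
#'   tolerance), `t_avg_used`, and the `running` average trace.
#' @export
max_lyapunov <- function(r_hat, W_E, eps = 0.1, node = node_params(),
                         m = 10, cfg = lyap_config()) {
  stopifnot(inherits(cfg, "wc_lyap_config"))
  r_hat <- as.complex(r_hat)
  h <- lyap_step(cfg, eps, m)
  node0 <- lyap_node0(W_E, node)
  t_avg <- cfg$t_avg
  repeat {
    res <- lyap_chain_cpp(Re(r_hat), Im(r_hat), W_E, eps, node$p, node$a,
                          node$tau1, node$tau2, node$W_IE, as.integer(m), h,
                          cfg$transient, cfg$var_skip, t_avg, cfg$renorm_dt,
                          node0, cfg$conv_tol)
    if (res$converged || !cfg$extend || t_avg >= cfg$max_avg) break
    t_avg <- min(2 * t_avg, cfg$max_avg)
  }
  structure(list(lambda = res$lambda, converged = res$converged,
                 marginal = abs(res$lambda) < cfg$conv_tol,
                 t_avg_used = t_avg, running = res$running,
                 r_hat = r_hat, W_E = W_E, eps = eps, m = m),
            class = "wc_lyap")
}

#' @export
print.wc_lyap <- function(x, ...) {
  cat(sprintf("<wc_lyap> lambda = %.5f (r_hat = %s, eps = %g)%s%s\n",
              x$lambda, format(x$r_hat, digits = 4), x$eps,
              if (x$marginal) " [marginal]" else "",
              if (!x$converged) " [NOT converged]" else ""))
  invisible(x)
}

#' @export
as.double.wc_lyap <- function(x, ...) x$lambda

#' Sign check by direct integration of the linear delayed variational system
#'
#' Independent cross-check of [max_lyapunov()]: the variational system is
#' integrated as a true linear DDE -- the delayed perturbation is read
#' from its own dense history, with no chain discretization -- and the
#' average exponential growth rate of the perturbation norm is measured
#' (renormalizing state and history together, which is exact for a
#' linear system). The result is classified by sign.
#'
#' @inheritParams max_lyapunov
#' @param band Rates within `(-band, band)` are classified `"marginal"`.
#' @return A list of class `wc_growth`: `rate`, `classification`
#'   (`"decayed"`, `"grew"` or `"marginal"`), `converged`.
#' @export
direct_dde_growth <- function(r_hat, W_E, eps = 0.1, node = node_params(),
                              cfg = lyap_config(), band = 1e-3) {
  stopifnot(inherits(cfg, "wc_lyap_config"))
  r_hat <- as.complex(r_hat)
  h <- if (is.null(cfg$step)) 0.01 else cfg$step
  if (eps > 0) h <- min(h, eps / 4)
  n <- max(1L, round(cfg$renorm_dt / h)); h <- cfg$renorm_dt / n
  res <- direct_dde_growth_cpp(Re(r_hat), Im(r_hat), W_E, eps, node$p,
                               node$a, node$tau1, node$tau2, node$W_IE, h,
                               cfg$transient, cfg$var_skip, cfg$t_avg,
                               cfg$renorm_dt, lyap_node0(W_E, node),
                               cfg$conv_tol)
  cls <- if (res$rate < -band) "decayed" else if (res$rate > band) "grew"
  else "marginal"
  structure(list(rate = res$rate, classification = cls,
                 converged = res$converged),
            class = "wc_growth")
}

#' @export
print.wc_growth <- function(x, ...) {
  cat(sprintf("<wc_growth> rate = %.5f (%s)\n", x$rate, x$classification))
  invisible(x)
}

#' Synchronous trajectory of a row-normalized network
#'
#' Integrates the single self-coupled node -- the system every node of a
#' row-normalized network with homogeneous delays follows when
#' synchronized -- and returns the post-transient trajectory with enough
#' lookback for delayed coefficient evaluation.
#'
#' @inheritParams max_lyapunov
#' @param transient Discarded settling time.
#' @param record Recorded window length.
#' @param record_every Output spacing.
#' @return A `wc_trajectory` with states `E`, `I`, `W_EI`; recording
#'   starts `eps` before the end of the transient so that delayed values
#'   within the window are available.
#' @export
synchronous_trajectory <- function(W_E, eps = 0.1, node = node_params(),
                                   transient = 500, record = 1500,
                                   record_every = 0.01) {
  integrate_single_node(W_E, eps, node, t_end = transient + record,
                        record_from = max(0, transient - eps - 1),
                        record_every = record_every)
}

#' Coefficients of the variational system along the synchronous solution
#'
#' `M1(t) = phi'(W_E * E_s(t - eps) - W_EI_s(t) * I_s(t))` (the gain at
#' the excitatory population's operating point) and
#' `M2(t) = W_IE * phi'(W_IE * E_s(t))`; both strictly positive.
#'
#' @param E_lag Synchronous excitatory activity at `t - eps`.
#' @param I,W_EI,E Synchronous states at `t`.
#' @param W_E Global coupling.
#' @param node A [node_params()] bundle.
#' @return List with numeric `M1`, `M2`.
#' @export
msf_coefficients <- function(E_lag, I, W_EI, E, W_E, node = node_params()) {
  list(M1 = phi_prime(W_E * E_lag - W_EI * I, node$a),
       M2 = node$W_IE * phi_prime(node$W_IE * E, node$a))
}

#' Right-hand side of the variational system at one eigenvalue
#'
#' Reference (pure-R) implementation of the transverse variational
#' equations around the synchronous solution, with the delayed
#' perturbation supplied by the caller -- either a chain tail or a dense
#' lookback. Used for structural tests; the production Lyapunov path
#' evaluates the same expressions in compiled code.
#'
#' @param t Time.
#' @param v Complex perturbation `(eta_x, eta_y, eta_z)`.
#' @param eta_x_lag Complex delayed perturbation `eta_x(t - eps)`.
#' @param r_hat Connectivity eigenvalue multiplying the delayed term.
#' @param sync Function `sync(s)` returning the synchronous state
#'   `c(E, I, W_EI)` at time `s`.
#' @param W_E,eps,node Model constants as elsewhere.
#' @return Complex derivative vector of length 3.
#' @export
variational_rhs <- function(t, v, eta_x_lag, r_hat, sync, W_E, eps = 0.1,
                            node = node_params()) {
  s_now <- sync(t)
  s_lag <- sync(t - eps)
  co <- msf_coefficients(s_lag[1], s_now[2], s_now[3], s_now[1], W_E, node)
  eta_x <- v[1]; eta_y <- v[2]; eta_z <- v[3]
  c((-eta_x + co$M1 * (r_hat * eta_x_lag - s_now[2] * eta_z -
                         s_now[3] * eta_y)) / node$tau1,
    -eta_y + co$M2 * eta_x,
    ((s_now[1] - node$p) * eta_y + s_now[2] * eta_x) / node$tau2)
}

#' Delay-line (chain) discretization matrix
#'
#' The delayed variable is approximated by advecting the live signal
#' through `m` cells: the head `x_1` is the live variable, interior
#' cells follow `x_n' = (x_{n-1} - x_{n+1}) * m / (2 eps)` for
#' `n = 2..m-1`, and the tail -- the delayed value -- follows
#' `x_m' = (x_{m-1} - x_m) * m / eps`. This routine returns the linear
#' operator of the driven cells (`x_2..x_m`) split into the internal
#' coupling matrix `A` and the input vector `b` multiplying the live
#' head, so the chain's response to a supplied head signal can be
#' studied on its own.
#'
#' @param eps Delay, `> 0`.
#' @param m Number of cells, `>= 2`.
#' @return List with `A` (`(m-1) x (m-1)`), `b` (length `m-1`), and `m`,
#'   `eps`.
#' @export
discretize_delay_line <- function(eps, m = 10) {
  if (eps <= 0)
    stop("the chain needs eps > 0; use the undelayed system instead",
         call. = FALSE)
  if (m < 2) stop("`m` must be at least 2", call. = FALSE)
  k <- m - 1 # driven cells x_2..x_m
  A <- matrix(0, k, k)
  b <- numeric(k)
  c2 <- m / (2 * eps); c1 <- m / eps
  if (m >= 3) for (n in 2:(m - 1)) { # interior cells (absent when m = 2)
    i <- n - 1
    if (n == 2) b[i] <- c2 else A[i, i - 1] <- c2
    A[i, i + 1] <- -c2
  }
  if (m == 2) b[k] <- c1 else A[k, k - 1] <- c1
  A[k, k] <- A[k, k] - c1
  list(A = A, b = b, m = m, eps = eps)
}

#' Master Stability Function over the scaled complex plane
#'
#' Evaluates [max_lyapunov()] on a grid of scaled eigenvalues
#' (`r_hat / W_E`) covering `[-lim, lim]^2` (each grid point is
#' multiplied back by `W_E` before entering the variational system),
#' exploiting conjugation
#' symmetry by computing the upper half plane and mirroring. The
#' zero-level boundary separates eigenvalues whose transverse
#' perturbations decay from those that grow.
#'
#' @inheritParams max_lyapunov
#' @param resolution Grid points per axis (odd keeps 0 on the grid).
#' @param lim Half-width of the grid.
#' @return A tibble of class `wc_msf` with columns `re`, `im`, `lambda`,
#'   `converged`, `marginal`; attribute `boundary` holds the zero-level
#'   contour(s) as a list of data frames.
#' @export
msf_region <- function(W_E, eps = 0.1, node = node_params(), m = 10,
                       cfg = lyap_config(), resolution = 41, lim = 1.1) {
  if (resolution < 5) stop("`resolution` is too coarse", call. = FALSE)
  if (resolution %% 2 == 0) resolution <- resolution + 1 # keep the real axis on the grid
  ax <- seq(-lim, lim, length.out = resolution)
  im_ax <- ax[ax > -1e-12] # upper half plane incl. axis; mirror the rest
  grid <- tidyr::expand_grid(re = ax, im = im_ax)
  vals <- purrr::pmap(grid, function(re, im) {
    l <- max_lyapunov(complex(real = re, imaginary = im) * W_E, W_E, eps,
                      node, m, cfg)
    tibble::tibble(lambda = l$lambda, converged = l$converged,
                   marginal = l$marginal)
  })
  upper <- dplyr::bind_cols(grid, dplyr::bind_rows(vals))
  lower <- dplyr::filter(upper, .data$im > 1e-12)
  lower$im <- -lower$im
  out <- dplyr::arrange(dplyr::bind_rows(upper, lower), .data$im, .data$re)
  lam <- matrix(out$lambda, nrow = resolution, ncol = resolution)
  boundary <- grDevices::contourLines(x = ax, y = ax, z = lam, levels = 0)
  boundary <- purrr::map(boundary, function(b)
    data.frame(re = b$x, im = b$y))
  attr(out, "boundary") <- boundary
  attr(out, "W_E") <- W_E
  attr(out, "eps") <- eps
  class(out) <- c("wc_msf", class(out))
  out
}

#' Predict synchronization of a network from its spectrum
#'
#' Evaluates the Master Stability Function at every eigenvalue of the
#' weight matrix transverse to the synchronous direction. The Perron
#' eigenvalue (scaled value 1, eigenvector all-ones) is excluded from
#' the verdict and reported separately: perturbations along it move the
#' network within the synchronous manifold, so its exponent is the
#' attractor's own leading exponent (about 0 on a limit cycle, positive
#' for chaos), not a desynchronizing direction. Conjugate eigenvalue
#' pairs are computed once and mirrored.
#'
#' @param W Row-normalized nonnegative weight matrix.
#' @inheritParams max_lyapunov
#' @param tol Verdict band: stable needs every transverse exponent below
#'   `-tol`; any exponent above `+tol` gives unstable; otherwise
#'   marginal.
#' @return A tibble of class `wc_sync_prediction`, one row per
#'   eigenvalue: `re_scaled`, `im_scaled`, `lambda`, `converged`, `role`
#'   (`"perron"` or `"transverse"`). Attribute `verdict` is
#'   `"stable"`, `"unstable"` or `"marginal"`; attribute `perron_lambda`
#'   is the synchronous attractor's exponent.
#' @export
predict_synchronization <- function(W, eps = 0.1, node = node_params(),
                                    m = 10, cfg = lyap_config(),
                                    tol = 1e-3) {
  rs <- rowSums(W)
  if (diff(range(rs)) > 1e-8 * max(abs(rs), 1))
    stop("`W` must be row-normalized (constant row sums)", call. = FALSE)
  W_E <- rs[1]
  sp <- spectrum(W, W_E)
  ev <- complex(real = sp$re, imaginary = sp$im)
  key <- round(complex(real = Re(ev), imaginary = abs(Im(ev))), 10)
  uniq <- !duplicated(key)
  lam <- rep(NA_real_, length(ev)); conv <- rep(NA, length(ev))
  cache <- list()
  for (i in seq_along(ev)) {
    k <- as.character(key[i])
    if (is.null(cache[[k]])) {
      l <- max_lyapunov(complex(real = Re(ev[i]), imaginary = abs(Im(ev[i]))),
                        W_E, eps, node, m, cfg)
      cache[[k]] <- l
    }
    lam[i] <- cache[[k]]$lambda
    conv[i] <- cache[[k]]$converged
  }
  out <- tibble::tibble(
    re_scaled = sp$re_scaled, im_scaled = sp$im_scaled,
    lambda = lam, converged = conv,
    role = ifelse(sp$is_perron, "perron", "transverse"))
  trans <- out$lambda[out$role == "transverse"]
  verdict <- if (length(trans) == 0 || all(trans < -tol)) "stable"
  else if (any(trans > tol)) "unstable" else "marginal"
  attr(out, "verdict") <- verdict
  attr(out, "perron_lambda") <-
    if (any(out$role == "perron")) out$lambda[out$role == "perron"][1]
  else NA_real_
  attr(out, "W_E") <- W_E
  attr(out, "eps") <- eps
  class(out) <- c("wc_sync_prediction", class(out))
  out
}

#' @export
print.wc_sync_prediction <- function(x, ...) {
  cat(sprintf(
    "<wc_sync_prediction> verdict: %s (W_E = %g, eps = %g); perron lambda = %.4f\n",
    attr(x, "verdict"), attr(x, "W_E"), attr(x, "eps"),
    attr(x, "perron_lambda")))
  print(tibble::as_tibble(x))
  invisible(x)
}
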