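#' Characteristic function of the linearized self-coupled node
#'
#' Linearizing the single self-coupled node about its equilibrium gives a
#' three-dimensional linear DDE whose nontrivial solutions
#' `exp(lambda t)` satisfy `char_fn(lambda) = 0`. The delayed
#' self-coupling enters through `r_hat * exp(-lambda * eps)`; for the
#' node itself `r_hat = W_E`, while substituting a connectivity
#' eigenvalue for `r_hat` gives the characteristic function of the
#' frozen-coefficient variational system used as the analytic oracle for
#' the Master Stability Function at the equilibrium.
#'
#' The gain constants are `M1 = phi'(phi_inv(p)) = a p (1 - p)` and
#' `M2 = W_IE * phi'(W_IE * p)`, with the equilibrium inhibitory activity
#' and weight entering the cross terms.
#'
#' @param lambda Complex argument (vectorized).
#' @param W_E Global coupling (sets the equilibrium inhibitory weight).
#' @param eps Delay.
#' @param node A [node_params()] bundle (supplies `W_IE`).
#' @param r_hat Coefficient of the delayed term; defaults to `W_E`.
#' @return Complex values of the characteristic determinant; conjugate
#'   symmetric in `lambda` for real `r_hat`.
#' @export
char_fn <- function(lambda, W_E, eps = 0, node = node_params(),
                    r_hat = W_E) {
  eq <- equilibrium(W_E, node)
  M1 <- node$a * node$p * (1 - node$p)
  M2 <- node$W_IE * phi_prime(node$W_IE * node$p, node$a)
  lambda <- as.complex(lambda)
  A <- (-1 + M1 * r_hat * exp(-lambda * eps)) / node$tau1
  b <- -M1 * eq$W_EI / node$tau1
  cc <- -M1 * eq$I / node$tau1
  (lambda - A) * lambda * (lambda + 1) - b * M2 * lambda -
    cc * eq$I * (lambda + 1) / node$tau2
}

# 3x3 Jacobian of the frozen-coefficient variational system with the
# delayed term treated as instantaneous scaled by `delay_factor`
# (exp(-lambda*eps) = 1 gives the eps = 0 Jacobian).
variational_jacobian <- function(W_E, node = node_params(), r_hat = W_E) {
  eq <- equilibrium(W_E, node)
  M1 <- node$a * node$p * (1 - node$p)
  M2 <- node$W_IE * phi_prime(node$W_IE * node$p, node$a)
  matrix(c(
    (-1 + M1 * r_hat) / node$tau1, -M1 * eq$W_EI / node$tau1,
    -M1 * eq$I / node$tau1,
    M2, -1, 0,
    eq$I / node$tau2, 0, 0), 3, 3, byrow = TRUE)
}

#' Rightmost characteristic root of the linearized node
#'
#' Finds the root of [char_fn()] with the largest real part by damped
#' Newton iteration started from a grid of seeds in the strip
#' `Re(lambda) in [-3, 1.5]`, `Im(lambda) in [0, omega_max]` (conjugate
#' roots are implied). Roots of the delay chain with more negative real
#' parts are irrelevant to stability and are not pursued. With `eps = 0`
#' the result is cross-checkable against the eigenvalues of the explicit
#' 3x3 Jacobian.
#'
#' @inheritParams char_fn
#' @param omega_max Upper edge of the imaginary-part search window. The
#'   node's oscillation frequencies are O(1) in model units, so the
#'   default 20 rad/time is generous.
#' @return The complex root with maximal real part; all distinct roots
#'   found are attached as attribute `roots`.
#' @export
rightmost_root <- function(W_E, eps = 0, node = node_params(), r_hat = W_E,
                           omega_max = 20) {
  if (eps == 0 && identical(Im(as.complex(r_hat)), 0)) {
    ev <- eigen(variational_jacobian(W_E, node, Re(r_hat)),
                only.values = TRUE)$values
    ev <- as.complex(ev)
    best <- ev[which.max(Re(ev))]
    attr(best, "roots") <- ev
    return(best)
  }
  f <- function(z) char_fn(z, W_E, eps, node, r_hat)
  seeds <- as.vector(outer(seq(-3, 1.5, by = 0.5),
                           1i * seq(0, omega_max, by = 1), `+`))
  roots <- complex(0)
  for (z0 in seeds) {
    z <- z0
    ok <- FALSE
    for (it in 1:60) {
      fz <- f(z)
      if (!is.finite(Re(fz)) || !is.finite(Im(fz))) break
      dh <- 1e-6
      df <- (f(z + dh) - f(z - dh)) / (2 * dh)
      if (Mod(df) < 1e-14) break
      dz <- fz / df
      if (Mod(dz) > 1) dz <- dz / Mod(dz) # damping far from a root
      z <- z - dz
      if (Mod(dz) < 1e-12) { ok <- TRUE; break }
    }
    if (ok && Mod(f(z)) < 1e-8 && Re(z) > -3.5 && abs(Im(z)) < omega_max + 2)
      roots <- c(roots, z)
  }
  if (!length(roots))
    stop("no characteristic root found in the search window", call. = FALSE)
  roots[Im(roots) < 0] <- Conj(roots[Im(roots) < 0])
  roots <- roots[!duplicated(round(roots, 7))]
  best <- roots[which.max(Re(roots))]
  attr(best, "roots") <- roots
  best
}

# eps = 0 Hopf anchor by brute force: bisection on W_E of the maximal real
# part of the 3x3 Jacobian eigenvalues. Independent of the transcendental
# root machinery, so it doubles as the no-delay oracle in tests.
hopf_eps0_bruteforce <- function(W_IE = 1, node = node_params(),
                                 bracket = c(1.2, 8), tol = 1e-10) {
  node <- node_params(p = node$p, a = node$a, tau1 = node$tau1,
                      tau2 = node$tau2, W_IE = W_IE)
  max_re <- function(W_E)
    max(Re(eigen(variational_jacobian(W_E, node), only.values = TRUE)$values))
  if (max_re(bracket[1]) >= 0 || max_re(bracket[2]) <= 0)
    stop("no stability change inside the W_E bracket", call. = FALSE)
  W <- stats::uniroot(max_re, bracket, tol = tol)$root
  ev <- eigen(variational_jacobian(W, node), only.values = TRUE)$values
  omega <- max(abs(Im(ev)))
  list(W_E_hopf = W, omega = omega)
}

#' Hopf boundary of the single self-coupled node
#'
#' Solves `char_fn(i * omega) = 0` (real and imaginary parts
#' simultaneously) for the critical coupling `W_E_hopf` and frequency
#' `omega` at which the equilibrium loses stability. The solver starts
#' from the exact no-delay solution (a cubic eigenvalue problem solved by
#' bisection) and continues in small delay increments with a damped
#' Newton step, which keeps it on the primary branch. The returned point
#' is validated by checking that the rightmost characteristic root
#' crosses the imaginary axis across `W_E_hopf`.
#'
#' Increasing the delay raises `W_E_hopf`: delayed self-excitation
#' postpones the onset of oscillations to stronger coupling.
#'
#' @param W_IE Excitatory-to-inhibitory weight at which to compute the
#'   boundary point.
#' @param eps Delay.
#' @param node A [node_params()] bundle (its `W_IE` is overridden by the
#'   `W_IE` argument).
#' @param validate Check the sign change of the rightmost root across the
#'   boundary (small extra cost).
#' @return A one-row tibble of class `wc_hopf_point`: `W_IE`,
#'   `W_E_hopf`, `omega`, `eps`.
#' @export
hopf_point <- function(W_IE = 1, eps = 0, node = node_params(),
                       validate = TRUE) {
  node <- node_params(p = node$p, a = node$a, tau1 = node$tau1,
                      tau2 = node$tau2, W_IE = W_IE)
  anchor <- hopf_eps0_bruteforce(W_IE, node)
  W <- anchor$W_E_hopf; om <- anchor$omega
  if (eps > 0) {
    cont <- seq(0, eps, length.out = max(2L, ceiling(eps / 0.02) + 1L))[-1]
    for (e in cont) {
      sol <- newton_hopf(W, om, e, node)
      W <- sol$W_E; om <- sol$omega
    }
  }
  if (validate) {
    lo <- Re(rightmost_root(W * 0.995, eps, node))
    hi <- Re(rightmost_root(W * 1.005, eps, node))
    if (!(lo < 0 && hi > 0))
      warning(sprintf(
        "rightmost root does not change sign across W_E_hopf = %.6f", W))
  }
  out <- tibble::tibble(W_IE = W_IE, W_E_hopf = W, omega = om, eps = eps)
  class(out) <- c("wc_hopf_point", class(out))
  out
}

newton_hopf <- function(W0, om0, eps, node, max_it = 80) {
  g <- function(x) {
    v <- char_fn(1i * x[2], x[1], eps, node)
    c(Re(v), Im(v))
  }
  x <- c(W0, om0)
  for (it in seq_len(max_it)) {
    fx <- g(x)
    if (sqrt(sum(fx^2)) < 1e-11) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      dx <- x; dh <- 1e-7 * max(1, abs(x[j])); dx[j] <- dx[j] + dh
      J[, j] <- (g(dx) - fx) / dh
    }
    step <- tryCatch(solve(J, fx), error = function(e)
      stop("Newton step singular; use a finer delay continuation",
           call. = FALSE))
    damp <- 1
    while (damp > 1e-4 &&
           sqrt(sum(g(x - damp * step)^2)) > sqrt(sum(fx^2)))
      damp <- damp / 2
    x <- x - damp * step
    if (x[2] <= 0) x[2] <- om0 # keep on the positive-frequency branch
  }
  if (sqrt(sum(g(x)^2)) > 1e-8)
    stop("Hopf Newton iteration did not converge; use a finer continuation",
         call. = FALSE)
  list(W_E = x[1], omega = x[2])
}

#' Hopf boundary curve over a grid of inhibitory couplings
#'
#' Runs [hopf_point()] along `W_IE_grid` with warm starts, returning the
#' locus `W_E_hopf = g(W_IE)` at a fixed delay.
#'
#' @param W_IE_grid Increasing numeric grid of `W_IE` values.
#' @param eps Delay.
#' @param node A [node_params()] bundle.
#' @return A tibble of class `wc_hopf_curve` with one row per grid point:
#'   `W_IE`, `W_E_hopf`, `omega`, `eps`.
#' @export
hopf_curve <- function(W_IE_grid, eps = 0, node = node_params()) {
  rows <- purrr::map(W_IE_grid, function(w)
    hopf_point(W_IE = w, eps = eps, node = node, validate = FALSE))
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wc_hopf_curve", class(out))
  out
}

#' Orbit diagram of the single self-coupled node
#'
#' For each coupling on the grid, simulates the node, discards a
#' transient, collects the local maxima of `E(t)` over the recording
#' window, and clusters them within a tolerance. One cluster indicates a
#' simple limit cycle (or, with no maxima, a stable equilibrium); cluster
#' counts 2, 4, ... trace a period-doubling cascade; many unclustered
#' peaks indicate chaos. The cascade is present for small delays and
#' disappears at larger delays, where only a single-peak oscillation
#' survives past the Hopf point.
#'
#' @param W_E_grid Numeric grid of couplings.
#' @param eps Delay.
#' @param node A [node_params()] bundle.
#' @param transient Time discarded before recording; long enough for the
#'   homeostatic weight (time constant `tau2`) to settle on the
#'   attractor.
#' @param record Length of the recording window.
#' @param step Integrator step (`NULL` for the default).
#' @param cluster_tol Peaks closer than this (in `E` units) belong to one
#'   cluster.
#' @return A tibble of class `wc_orbit_diagram`: one row per `(W_E,
#'   cluster)` with columns `W_E`, `peak` (cluster mean), `n_in_cluster`,
#'   `n_clusters`; couplings whose trajectory diverged are flagged in the
#'   `diverged` column with `NA` peaks. Attributes record `eps` and the
#'   simulation settings.
#' @export
orbit_diagram <- function(W_E_grid, eps = 0.1, node = node_params(),
                          transient = 500, record = 1500, step = NULL,
                          cluster_tol = 1e-3) {
  rows <- purrr::map(W_E_grid, function(W_E) {
    tr <- tryCatch(
      integrate_single_node(W_E, eps, node, t_end = transient + record,
                            step = step, record_from = transient,
                            record_every = 0.02),
      error = function(e) NULL)
    if (is.null(tr))
      return(tibble::tibble(W_E = W_E, peak = NA_real_, n_in_cluster = 0L,
                            n_clusters = NA_integer_, diverged = TRUE))
    pk <- find_peaks(tr$t, tr$y[, "E"])
    cl <- cluster_peaks(pk, cluster_tol)
    if (!nrow(cl))
      return(tibble::tibble(W_E = W_E, peak = NA_real_, n_in_cluster = 0L,
                            n_clusters = 0L, diverged = FALSE))
    tibble::tibble(W_E = W_E, peak = cl$peak, n_in_cluster = cl$n,
                   n_clusters = nrow(cl), diverged = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "eps") <- eps
  attr(out, "settings") <- list(transient = transient, record = record,
                                cluster_tol = cluster_tol)
  class(out) <- c("wc_orbit_diagram", class(out))
  out
}

# Local maxima with quadratic vertex refinement on a uniformly sampled
# series; endpoints excluded.
find_peaks <- function(t, x) {
  n <- length(x)
  if (n < 3) return(numeric(0))
  i <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  i <- i[i > 1 & i < n]
  if (!length(i)) return(numeric(0))
  a <- x[i - 1]; b <- x[i]; cc <- x[i + 1]
  denom <- a - 2 * b + cc
  refine <- b - (a - cc)^2 / (8 * denom)
  ifelse(abs(denom) > 1e-14, refine, b)
}

# Sort the peak values and split at gaps larger than tol.
cluster_peaks <- function(peaks, tol) {
  if (!length(peaks)) return(tibble::tibble(peak = numeric(0), n = integer(0)))
  s <- sort(peaks)
  grp <- cumsum(c(1, diff(s) > tol))
  tibble::tibble(
    peak = as.numeric(tapply(s, grp, mean)),
    n = as.integer(tapply(s, grp, length)))
}

#' Detect period-doubling transitions in an orbit diagram
#'
#' Scans the coupling grid for intervals where the number of peak
#' clusters doubles (1 to 2, 2 to 4, ...), the signature of a
#' period-doubling bifurcation between adjacent grid points.
#'
#' @param diagram An [orbit_diagram()] computed on a monotone grid.
#' @return A tibble with one row per doubling transition: `W_E_lo`,
#'   `W_E_hi`, `from`, `to` (cluster counts). Empty when no doubling
#'   occurs.
#' @export
detect_period_doubling <- function(diagram) {
  stopifnot(inherits(diagram, "wc_orbit_diagram"))
  counts <- dplyr::distinct(
    dplyr::select(tibble::as_tibble(diagram), "W_E", "n_clusters", "diverged"))
  counts <- counts[order(counts$W_E), ]
  counts <- counts[!counts$diverged & !is.na(counts$n_clusters) &
                     counts$n_clusters > 0, ]
  if (nrow(counts) < 2)
    return(tibble::tibble(W_E_lo = numeric(0), W_E_hi = numeric(0),
                          from = integer(0), to = integer(0)))
  from <- counts$n_clusters[-nrow(counts)]
  to <- counts$n_clusters[-1]
  hit <- which(to == 2L * from)
  tibble::tibble(W_E_lo = counts$W_E[hit], W_E_hi = counts$W_E[hit + 1],
                 from = from[hit], to = to[hit])
}
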