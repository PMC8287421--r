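#' Simulate a network and measure synchrony
#'
#' Integrates the network from a constant history at the equilibrium plus
#' a seeded uniform perturbation (testing local stability of the
#' synchronous state, the same question the Master Stability Function
#' answers), then summarizes the final window: `sync_error` is the
#' time-averaged maximal pairwise spread `max_kj |E_k - E_j|`, and the
#' network is called synchronized when it falls below `threshold`.
#'
#' @param spec A [network_spec()].
#' @param perturb_scale Half-width of the uniform perturbation applied to
#'   every state component of every node's history.
#' @param seed Seed for the perturbation.
#' @param t_end Simulated time.
#' @param window_frac Fraction of the run (at the end) used for metrics.
#' @param threshold Synchrony threshold on `sync_error`.
#' @param step,record_every Passed to [integrate_network()].
#' @param keep_trajectory Attach the recorded trajectory as an attribute.
#' @return A one-row tibble of class `wc_sync_metrics`: `N`, `W_E`,
#'   `eps_mean`, `sync_error`, `is_synchronized`, `diverged`, `seed`.
#'   With `keep_trajectory = TRUE` the trajectory is in
#'   `attr(, "trajectory")`.
#' @export
simulate_and_measure <- function(spec, perturb_scale = 1e-2, seed = 1,
                                 t_end = 2000, window_frac = 0.2,
                                 threshold = 1e-3, step = NULL,
                                 record_every = 0.05,
                                 keep_trajectory = FALSE) {
  stopifnot(inherits(spec, "wc_network"))
  N <- spec$N
  eq <- equilibrium(spec$W_E, spec$node)
  pert <- with_seed(seed, matrix(runif(3 * N, -perturb_scale, perturb_scale),
                                 3, N))
  history <- list(E = eq$E + pert[1, ], I = eq$I + pert[2, ],
                  W_EI = eq$W_EI + pert[3, ])
  record_from <- t_end * (1 - window_frac)
  tr <- tryCatch(
    integrate_network(spec, history, t_end = t_end, step = step,
                      record_from = record_from,
                      record_every = record_every),
    error = function(e) e)
  if (inherits(tr, "error")) {
    out <- tibble::tibble(N = N, W_E = spec$W_E,
                          eps_mean = mean(spec$eps[spec$W_EE > 0]),
                          sync_error = NA_real_, is_synchronized = NA,
                          diverged = TRUE, seed = seed)
    class(out) <- c("wc_sync_metrics", class(out))
    return(out)
  }
  Emat <- tr$y[, seq_len(N), drop = FALSE]
  spread <- if (N > 1)
    apply(Emat, 1, max) - apply(Emat, 1, min) else rep(0, nrow(Emat))
  sync_error <- mean(spread)
  out <- tibble::tibble(N = N, W_E = spec$W_E,
                        eps_mean = mean(spec$eps[spec$W_EE > 0]),
                        sync_error = sync_error,
                        is_synchronized = sync_error < threshold,
                        diverged = FALSE, seed = seed)
  if (keep_trajectory) attr(out, "trajectory") <- tr
  class(out) <- c("wc_sync_metrics", class(out))
  out
}

#' Discrete Hausdorff distance between two attractors
#'
#' Compares the post-transient `(E, I)` point cloud of a network's first
#' node with that of a reference trajectory (typically the single
#' self-coupled node at the same coupling): the largest distance from a
#' point of either cloud to the nearest point of the other. Small values
#' mean the network landed on the reference attractor.
#'
#' @param traj,ref `wc_trajectory` objects; the `(E, I)` components are
#'   the first ones named `E*` and `I*`.
#' @param window Optional `c(from, to)` restricting both clouds in time.
#' @param max_points Clouds are thinned to at most this many points.
#' @return The Hausdorff distance in `(E, I)` units.
#' @export
attractor_distance <- function(traj, ref, window = NULL, max_points = 1500) {
  a <- attractor_cloud(traj, window, max_points)
  b <- attractor_cloud(ref, window, max_points)
  d2 <- outer(a[, 1], b[, 1], `-`)^2 + outer(a[, 2], b[, 2], `-`)^2
  max(sqrt(max(apply(d2, 1, min))), sqrt(max(apply(d2, 2, min))))
}

attractor_cloud <- function(traj, window, max_points) {
  stopifnot(inherits(traj, "wc_trajectory"))
  Ecol <- grep("^E", traj$vars)[1]
  Icol <- grep("^I", traj$vars)[1]
  keep <- rep(TRUE, length(traj$t))
  if (!is.null(window)) {
    if (window[1] < traj$t[1] - 1e-9 ||
        window[2] > traj$t[length(traj$t)] + 1e-9)
      stop("window outside the trajectory span", call. = FALSE)
    keep <- traj$t >= window[1] & traj$t <= window[2]
  }
  pts <- cbind(traj$y[keep, Ecol], traj$y[keep, Icol])
  # keep the final contiguous block at full recording density: sampling
  # gaps along the orbit, not attractor mismatch, would otherwise
  # dominate the Hausdorff distance
  if (nrow(pts) > max_points)
    pts <- pts[(nrow(pts) - max_points + 1):nrow(pts), ]
  pts
}

#' Pairwise phase lags from cross-correlation
#'
#' Estimates, for each node, the time lag of its excitatory trace
#' relative to node 1 as the argmax of the cross-correlation over the
#' recorded window.
#'
#' @param traj A network `wc_trajectory`.
#' @param max_lag Largest lag searched, in time units.
#' @return Numeric vector of per-node lags (node 1 is 0).
#' @export
phase_lags <- function(traj, max_lag = 2) {
  stopifnot(inherits(traj, "wc_trajectory"))
  Ecols <- grep("^E", traj$vars)
  dt <- traj$t[2] - traj$t[1]
  L <- min(round(max_lag / dt), length(traj$t) - 2)
  x1 <- traj$y[, Ecols[1]]
  vapply(Ecols, function(cj) {
    cc <- stats::ccf(traj$y[, cj], x1, lag.max = L, plot = FALSE,
                     demean = TRUE)
    cc$lag[which.max(cc$acf)] * dt
  }, numeric(1))
}

#' Scan ring sizes for delay-induced desynchronization
#'
#' For each ring size, evaluates the Master Stability Function at the
#' ring's transverse eigenvalues and confirms the verdict with a direct
#' network simulation, over a set of global couplings. As the ring grows,
#' its second-largest scaled eigenvalue moves along the unit circle
#' toward 1, where the delayed stability region recedes, so sufficiently
#' large rings lose synchrony under delay while all sizes remain stable
#' without it.
#'
#' @param N_range Ring sizes to scan (ordered).
#' @param W_E_list Global couplings to test.
#' @param eps Delay.
#' @param node A [node_params()] bundle.
#' @param topology `"ring"` (unidirectional) or `"lattice"` (symmetric
#'   nearest-neighbour).
#' @param m,cfg Master-Stability settings ([lyap_config()]).
#' @param sim_args List of overrides for [simulate_and_measure()].
#' @return A tibble of class `wc_threshold_scan`, one row per
#'   `(N, W_E)`: `msf_verdict`, `sim_synchronized`, `agree`. Attributes
#'   `smallest_desync_msf`, `smallest_desync_sim`,
#'   `smallest_desync_confirmed` (both methods desynchronized; `NA` when
#'   none) summarize the scan.
#' @export
ring_threshold_scan <- function(N_range = 2:10,
                                W_E_list = c(2.05, 2.115, 2.25),
                                eps = 0.1, node = node_params(),
                                topology = c("ring", "lattice"), m = 10,
                                cfg = lyap_config(), sim_args = list()) {
  topology <- match.arg(topology)
  gen <- if (topology == "ring") ring_unidirectional else ring_lattice
  grid <- tidyr::expand_grid(N = N_range, W_E = W_E_list)
  rows <- purrr::pmap(grid, function(N, W_E) {
    W <- gen(N, W_E)
    pred <- predict_synchronization(W, eps = eps, node = node, m = m,
                                    cfg = cfg)
    sim <- do.call(simulate_and_measure,
                   c(list(spec = network_spec(W, eps = eps, node = node)),
                     sim_args))
    tibble::tibble(
      N = N, W_E = W_E, eps = eps,
      msf_verdict = attr(pred, "verdict"),
      max_transverse_lambda =
        max(pred$lambda[pred$role == "transverse"], -Inf),
      perron_lambda = attr(pred, "perron_lambda"),
      sim_sync_error = sim$sync_error,
      sim_synchronized = sim$is_synchronized,
      agree = (attr(pred, "verdict") == "stable") == sim$is_synchronized |
        attr(pred, "verdict") == "marginal")
  })
  out <- dplyr::bind_rows(rows)
  by_N <- dplyr::summarise(
    dplyr::group_by(out, .data$N),
    msf_desync = any(.data$msf_verdict == "unstable"),
    sim_desync = any(!.data$sim_synchronized),
    both = any(.data$msf_verdict == "unstable" & !.data$sim_synchronized))
  first_or_na <- function(v) if (any(v)) min(by_N$N[v]) else NA_integer_
  attr(out, "smallest_desync_msf") <- first_or_na(by_N$msf_desync)
  attr(out, "smallest_desync_sim") <- first_or_na(by_N$sim_desync)
  attr(out, "smallest_desync_confirmed") <- first_or_na(by_N$both)
  attr(out, "smallest_desync_either") <-
    first_or_na(by_N$msf_desync | by_N$sim_desync)
  attr(out, "topology") <- topology
  class(out) <- c("wc_threshold_scan", class(out))
  out
}

#' @export
print.wc_threshold_scan <- function(x, ...) {
  cat(sprintf(
    "<wc_threshold_scan> %s, smallest desynchronized N: MSF %s, sim %s, confirmed %s\n",
    attr(x, "topology"),
    format(attr(x, "smallest_desync_msf")),
    format(attr(x, "smallest_desync_sim")),
    format(attr(x, "smallest_desync_confirmed"))))
  print(tibble::as_tibble(x))
  invisible(x)
}

#' Heterogeneous-delay robustness study
#'
#' Repeats the homogeneous-delay simulations with per-edge delays drawn
#' from a Beta distribution renormalized to the target mean, and compares
#' each run with its homogeneous counterpart. Exact coincidence of nodes
#' is impossible with unequal delays, so synchrony is assessed by the
#' attractor distance to the homogeneous run and the largest pairwise
#' phase lag (expected on the order of the delays themselves), rather
#' than by the raw pairwise spread.
#'
#' @param topology `"ring"` or `"random"`.
#' @param N_list Network sizes.
#' @param mean_eps Target mean delay.
#' @param W_E Global coupling.
#' @param seeds Integer vector: one heterogeneous sample per seed.
#' @param node A [node_params()] bundle.
#' @param alpha,beta Beta shapes for [heterogeneous_delays()].
#' @param dist_threshold Attractor-distance bound for calling the
#'   heterogeneous run synchronized onto the homogeneous attractor.
#' @param lag_factor Phase-lag bound, in multiples of the largest sampled
#'   delay.
#' @param t_end Simulated time per run.
#' @return A tibble of class `wc_het_study`, one row per
#'   `(topology, N, seed)` with the homogeneous verdict, the attractor
#'   distance, the maximal phase lag, and the resulting heterogeneous
#'   verdict.
#' @export
heterogeneous_delay_study <- function(topology = c("ring", "random"),
                                      N_list = c(6, 7, 8), mean_eps = 0.1,
                                      W_E = 2.115, seeds = 1:5,
                                      node = node_params(), alpha = 2,
                                      beta = 2, dist_threshold = 0.05,
                                      lag_factor = 5, t_end = 2000) {
  topology <- match.arg(topology)
  rows <- list()
  for (N in N_list) {
    W <- if (topology == "ring") ring_unidirectional(N, W_E)
    else random_row_normalized(N, W_E, seed = N)
    hom_spec <- network_spec(W, eps = mean_eps, node = node)
    hom <- simulate_and_measure(hom_spec, t_end = t_end,
                                keep_trajectory = TRUE)
    hom_tr <- attr(hom, "trajectory")
    for (s in seeds) {
      dl <- heterogeneous_delays(W, mean_eps, alpha, beta, seed = s)
      het_spec <- network_spec(W, eps = dl, node = node)
      het <- simulate_and_measure(het_spec, t_end = t_end, seed = s,
                                  keep_trajectory = TRUE)
      het_tr <- attr(het, "trajectory")
      if (het$diverged || hom$diverged) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          topology = topology, N = N, seed = s, W_E = W_E,
          mean_eps = mean_eps, hom_synchronized = hom$is_synchronized,
          attractor_dist = NA_real_, max_phase_lag = NA_real_,
          max_delay = max(dl$eps), het_synchronized = NA, diverged = TRUE)
        next
      }
      dist <- attractor_distance(het_tr, hom_tr)
      lags <- phase_lags(het_tr, max_lag = max(2, 5 * max(dl$eps)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        topology = topology, N = N, seed = s, W_E = W_E,
        mean_eps = mean_eps, hom_synchronized = hom$is_synchronized,
        attractor_dist = dist, max_phase_lag = max(abs(lags)),
        max_delay = max(dl$eps),
        het_synchronized = dist < dist_threshold &
          max(abs(lags)) <= lag_factor * max(dl$eps),
        diverged = FALSE)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("wc_het_study", class(out))
  out
}

#' Run a packaged end-to-end study
#'
#' Orchestrates the package's four standard studies:
#' \describe{
#'   \item{`"network_zoo"`}{random network, ring and single node at one
#'     delay: synchrony metrics and attractor distances to the single
#'     node.}
#'   \item{`"single_node"`}{Hopf boundary points per delay plus orbit
#'     diagrams at a small and a large delay.}
#'   \item{`"msf_rings"`}{Master Stability verdicts and simulations for
#'     small rings across couplings, plus MSF boundary data.}
#'   \item{`"heterogeneous"`}{the heterogeneous-delay robustness study.}
#' }
#' Every seed and tolerance used is captured in the returned manifest;
#' when `out_dir` is given, each result table is also written as CSV
#' together with a `manifest.yaml`, and re-running with the same config
#' reproduces the files bit-for-bit.
#'
#' @param name One of `"network_zoo"`, `"single_node"`, `"msf_rings"`,
#'   `"heterogeneous"`.
#' @param config Named list of overrides merged over the study defaults
#'   (see the manifest of a default run for the available keys).
#' @param out_dir Optional output directory for CSVs and the manifest.
#' @return A list of class `wc_experiment_report`: `name`, `manifest`
#'   (all parameters), `results` (named list of tibbles), `files`
#'   (paths written, if any).
#' @export
run_experiment <- function(name = c("network_zoo", "single_node",
                                    "msf_rings", "heterogeneous"),
                           config = list(), out_dir = NULL) {
  name <- match.arg(name)
  runner <- switch(name,
                   network_zoo = experiment_network_zoo,
                   single_node = experiment_single_node,
                   msf_rings = experiment_msf_rings,
                   heterogeneous = experiment_heterogeneous)
  res <- runner(config)
  report <- structure(list(name = name, manifest = res$manifest,
                           results = res$results, files = character(0)),
                      class = "wc_experiment_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in names(res$results)) {
      path <- file.path(out_dir, paste0(name, "_", nm, ".csv"))
      write.csv(tibble::as_tibble(res$results[[nm]]), path,
                row.names = FALSE)
      files <- c(files, path)
    }
    man_path <- file.path(out_dir, paste0(name, "_manifest.yaml"))
    yaml::write_yaml(res$manifest, man_path)
    report$files <- c(files, man_path)
  }
  report
}

#' @export
print.wc_experiment_report <- function(x, ...) {
  cat(sprintf("<wc_experiment_report> %s: %s\n", x$name,
              paste(names(x$results), collapse = ", ")))
  invisible(x)
}

merge_config <- function(defaults, config) {
  for (k in names(config)) defaults[[k]] <- config[[k]]
  defaults
}

experiment_network_zoo <- function(config) {
  cf <- merge_config(list(
    N_random = 10, N_ring = 8, W_E = 2.25, eps = 0.1, seed = 1,
    t_end = 2000, node = node_params()), config)
  single <- integrate_single_node(cf$W_E, cf$eps, cf$node, t_end = cf$t_end,
                                  record_from = cf$t_end * 0.8)
  conds <- list(
    random = random_row_normalized(cf$N_random, cf$W_E, seed = cf$seed),
    ring = ring_unidirectional(cf$N_ring, cf$W_E))
  rows <- purrr::imap(conds, function(W, nm) {
    met <- simulate_and_measure(network_spec(W, eps = cf$eps, node = cf$node),
                                seed = cf$seed, t_end = cf$t_end,
                                keep_trajectory = TRUE)
    dist <- if (!met$diverged)
      attractor_distance(attr(met, "trajectory"), single) else NA_real_
    dplyr::mutate(tibble::as_tibble(met), topology = nm,
                  attractor_dist_to_single = dist)
  })
  list(manifest = cf[names(cf) != "node"],
       results = list(metrics = dplyr::bind_rows(rows)))
}

experiment_single_node <- function(config) {
  cf <- merge_config(list(
    eps_hopf = c(0, 0.1, 0.3, 0.5), W_IE = 1,
    eps_orbit = c(0.1, 0.4), W_E_grid = seq(2, 3, by = 0.02),
    transient = 500, record = 1500, node = node_params()), config)
  hopf <- dplyr::bind_rows(purrr::map(cf$eps_hopf, function(e)
    hopf_point(W_IE = cf$W_IE, eps = e, node = cf$node, validate = FALSE)))
  orbits <- purrr::map(cf$eps_orbit, function(e)
    orbit_diagram(cf$W_E_grid, eps = e, node = cf$node,
                  transient = cf$transient, record = cf$record))
  names(orbits) <- paste0("orbit_eps_", cf$eps_orbit)
  pd <- purrr::imap(orbits, function(o, nm)
    dplyr::mutate(detect_period_doubling(o), eps = attr(o, "eps")))
  list(manifest = cf[names(cf) != "node"],
       results = c(list(hopf = hopf), orbits,
                   list(period_doubling = dplyr::bind_rows(pd))))
}

experiment_msf_rings <- function(config) {
  cf <- merge_config(list(
    N_range = c(2, 7, 8), W_E_list = c(2.05, 2.115, 2.25), eps = 0.1,
    m = 10, node = node_params(), cfg = lyap_config()), config)
  scan <- ring_threshold_scan(cf$N_range, cf$W_E_list, cf$eps, cf$node,
                              topology = "ring", m = cf$m, cfg = cf$cfg)
  list(manifest = c(cf[!(names(cf) %in% c("node", "cfg"))],
                    list(lyap = unclass(cf$cfg))),
       results = list(ring_scan = tibble::as_tibble(scan)))
}

experiment_heterogeneous <- function(config) {
  cf <- merge_config(list(
    topologies = c("ring", "random"), N_list = c(6, 7, 8), mean_eps = 0.1,
    W_E = 2.115, seeds = 1:5, node = node_params()), config)
  res <- dplyr::bind_rows(purrr::map(cf$topologies, function(tp)
    heterogeneous_delay_study(tp, cf$N_list, cf$mean_eps, cf$W_E, cf$seeds,
                              node = cf$node)))
  list(manifest = cf[names(cf) != "node"],
       results = list(heterogeneous = res))
}
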