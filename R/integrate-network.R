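#' Integrate a delay-coupled Wilson-Cowan network
#'
#' Fixed-step RK4 with cubic Hermite dense output for the delayed
#' excitatory lookups (the compiled counterpart of [integrate_dde()],
#' specialized to the network right-hand side). Heterogeneous lags are
#' honored exactly: each pair `(k, j)` reads `E_j(t - eps[k, j])` from the
#' dense solution, with no rounding of lags to the grid. With homogeneous
#' delays and identical per-node histories the nodes remain identical for
#' all time (invariance of the synchronous manifold), up to roundoff.
#'
#' @param spec A [network_spec()].
#' @param history Constant per-node history: list with numeric vectors
#'   `E`, `I`, `W_EI` (length `N`, or length 1 to recycle). Defaults to
#'   the network equilibrium.
#' @param t_end Final time (integration starts at 0 with the constant
#'   history on `[-max(eps), 0]`).
#' @param step Step size; capped at `min(0.01, min positive lag / 4)` and
#'   aligned so the smallest lag is an integer number of steps.
#' @param record_from Discard output before this time (the states are
#'   still integrated; only recording is suppressed).
#' @param record_every Spacing of recorded output points (multiple of the
#'   step).
#' @return A `wc_trajectory` with states `E1..EN, I1..IN, W_EI1..W_EIN`.
#' @examples
#' net <- network_spec(ring_unidirectional(3, 2.115), eps = 0.1)
#' tr <- integrate_network(net, t_end = 10)
#' @export
integrate_network <- function(spec, history = NULL, t_end = 2000,
                              step = NULL, record_from = 0,
                              record_every = 0.05) {
  stopifnot(inherits(spec, "wc_network"))
  N <- spec$N
  if (is.null(history)) {
    eq <- equilibrium(spec$W_E, spec$node)
    history <- list(E = rep(eq$E, N), I = rep(eq$I, N),
                    W_EI = rep(eq$W_EI, N))
  }
  E0 <- rep_len(history$E, N)
  I0 <- rep_len(history$I, N)
  W0 <- rep_len(history$W_EI, N)
  h <- resolve_step(step, spec$eps)
  stride <- max(1L, round(record_every / h))
  # land on or just past t_end, on the recording grid, so the full
  # requested span is covered by recorded points
  t_end <- ceiling(t_end / (stride * h) - 1e-9) * stride * h
  sol <- sim_wc_network_cpp(spec$W_EE, spec$eps, spec$node$p, spec$node$a,
                            spec$node$tau1, spec$node$tau2, spec$node$W_IE,
                            E0, I0, W0, t_end, h, record_from, stride)
  assemble_network_trajectory(sol, spec)
}

resolve_step <- function(step, eps) {
  pos <- eps[eps > 0]
  base <- if (is.null(step)) 0.01 else step
  if (!length(pos)) return(base)
  align_step(base, pos)
}

# Build a wc_trajectory from the compiled output; derivatives of I and
# W_EI follow from the model in closed form, so the dense interpolant is
# available for every state.
assemble_network_trajectory <- function(sol, spec) {
  N <- spec$N
  nd <- spec$node
  E <- sol$E; I <- sol$I; W <- sol$W_EI
  dI <- -I + phi(nd$W_IE * E, nd$a)
  dW <- I * (E - nd$p) / nd$tau2
  vars <- c(paste0("E", 1:N), paste0("I", 1:N), paste0("W_EI", 1:N))
  y <- cbind(E, I, W)
  f <- cbind(sol$dE, dI, dW)
  tr <- new_trajectory(sol$t, y, f, vars)
  tr$step <- sol$t[2] - sol$t[1]
  attr(tr, "spec") <- spec
  tr
}

#' Integrate the single self-coupled node
#'
#' Convenience wrapper for the `N = 1` network whose one node feeds back
#' to itself with weight `W_E` and delay `eps` -- the system governing
#' the synchronous solution of every row-normalized network with
#' homogeneous delays.
#'
#' @param W_E Self-coupling weight.
#' @param eps Self-coupling delay (0 gives the instantaneous node).
#' @param node A [node_params()] bundle.
#' @param history Constant history `c(E, I, W_EI)`; defaults to the
#'   equilibrium nudged by `+0.01` in `E`, which seeds convergence onto
#'   the stable attractor.
#' @inheritParams integrate_network
#' @return A `wc_trajectory` with states `E`, `I`, `W_EI`.
#' @export
integrate_single_node <- function(W_E, eps = 0, node = node_params(),
                                  history = NULL, t_end = 2000, step = NULL,
                                  record_from = 0, record_every = 0.05) {
  if (is.null(history)) {
    eq <- equilibrium(W_E, node)
    history <- c(eq$E + 0.01, eq$I, eq$W_EI)
  }
  spec <- network_spec(matrix(W_E, 1, 1), eps = eps, node = node)
  tr <- integrate_network(spec,
                          history = list(E = history[1], I = history[2],
                                         W_EI = history[3]),
                          t_end = t_end, step = step,
                          record_from = record_from,
                          record_every = record_every)
  colnames(tr$y) <- colnames(tr$f) <- tr$vars <- c("E", "I", "W_EI")
  tr
}
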