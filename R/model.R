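#' Specify a delay-coupled Wilson-Cowan network
#'
#' A network is an `N x N` nonnegative excitatory weight matrix `W_EE`
#' whose rows all sum to the global coupling `W_E`, an `N x N` matrix of
#' nonnegative conduction delays `eps` (entry `[k, j]` delays the signal
#' from node `j` to node `k`), and a shared [node_params()] bundle. The
#' constant row sum guarantees that the network admits an exactly
#' synchronous solution governed by the single self-coupled node.
#'
#' @param W_EE `N x N` nonnegative weight matrix with constant row sums.
#' @param eps Delay specification: a single nonnegative number (homogeneous
#'   delays), an `N x N` nonnegative matrix, or a [heterogeneous_delays()]
#'   sample.
#' @param node A [node_params()] bundle shared by all nodes.
#' @param W_E Optional expected row sum; if supplied, it is checked
#'   against the actual row sums.
#'
#' @return An object of class `wc_network`: list with elements `N`,
#'   `W_EE`, `eps` (matrix), `W_E`, `node`.
#' @examples
#' net <- network_spec(ring_unidirectional(5, W_E = 2.115), eps = 0.1)
#' net$W_E
#' @export
network_spec <- function(W_EE, eps = 0, node = node_params(), W_E = NULL) {
  stopifnot(is.matrix(W_EE), nrow(W_EE) == ncol(W_EE))
  N <- nrow(W_EE)
  if (any(!is.finite(W_EE)) || any(W_EE < 0))
    stop("`W_EE` must be nonnegative and finite", call. = FALSE)
  rs <- rowSums(W_EE)
  if (diff(range(rs)) > 1e-12 * max(abs(rs), 1))
    stop("rows of `W_EE` must all sum to the same global coupling W_E",
         call. = FALSE)
  if (!is.null(W_E) && abs(rs[1] - W_E) > 1e-12 * max(abs(W_E), 1))
    stop(sprintf("row sums (%g) do not match the requested W_E (%g)",
                 rs[1], W_E), call. = FALSE)
  if (inherits(eps, "wc_delay_sample")) eps <- eps$eps
  if (is.matrix(eps)) {
    stopifnot(nrow(eps) == N, ncol(eps) == N)
  } else {
    stopifnot(length(eps) == 1)
    eps <- matrix(eps, N, N)
  }
  if (any(!is.finite(eps)) || any(eps < 0))
    stop("delays must be nonnegative and finite", call. = FALSE)
  stopifnot(inherits(node, "wc_node"))
  structure(list(N = N, W_EE = W_EE, eps = eps, W_E = unname(rs[1]),
                 node = node),
            class = "wc_network")
}

#' @export
print.wc_network <- function(x, ...) {
  eps_rng <- range(x$eps)
  cat(sprintf("<wc_network> N = %d, W_E = %g, delays in [%g, %g]\n",
              x$N, x$W_E, eps_rng[1], eps_rng[2]))
  invisible(x)
}

#' Right-hand side of the delay-coupled network
#'
#' The model couples, per node `k`, an excitatory activity `E_k`, an
#' inhibitory activity `I_k`, and a homeostatic inhibitory weight
#' `W_EI_k`:
#' \deqn{\tau_1 E_k' = -E_k + \phi(\sum_j W^{EE}_{kj} E_j(t-\epsilon_{kj})
#'   - W^{EI}_k I_k)}
#' \deqn{I_k' = -I_k + \phi(W^{IE} E_k)}
#' \deqn{\tau_2 (W^{EI}_k)' = I_k (E_k - p)}
#' The homeostatic weight is not clamped: transiently negative values are
#' permitted, as in the model definition.
#'
#' Delayed excitatory activities are supplied through `delayed_E`, an
#' `N x N` matrix whose `[k, j]` entry is `E_j(t - eps[k, j])`, so the
#' same right-hand side serves the dense-history integrator and any
#' discretized variant.
#'
#' @param t Time (unused by the autonomous model; kept for the integrator
#'   contract).
#' @param state List with numeric vectors `E`, `I`, `W_EI` of length `N`.
#' @param delayed_E `N x N` matrix of delayed excitatory activities.
#' @param spec A [network_spec()].
#' @return List with vectors `dE`, `dI`, `dW_EI`.
#' @export
network_rhs <- function(t, state, delayed_E, spec) {
  stopifnot(inherits(spec, "wc_network"))
  N <- spec$N
  E <- state$E; I <- state$I; W_EI <- state$W_EI
  if (length(E) != N || length(I) != N || length(W_EI) != N)
    stop("state vectors must have length N", call. = FALSE)
  if (!is.matrix(delayed_E) || any(dim(delayed_E) != N))
    stop("`delayed_E` must be an N x N matrix", call. = FALSE)
  nd <- spec$node
  drive <- rowSums(spec$W_EE * delayed_E)
  list(
    dE = (-E + phi(drive - W_EI * I, nd$a)) / nd$tau1,
    dI = -I + phi(nd$W_IE * E, nd$a),
    dW_EI = I * (E - nd$p) / nd$tau2
  )
}

#' Right-hand side of the single self-coupled node
#'
#' The synchronous solution of any row-normalized network obeys the
#' equations of one node coupled to itself with weight `W_E` and delay
#' `eps`; this is the `N = 1` reduction of [network_rhs()].
#'
#' @param t Time (unused; integrator contract).
#' @param state Numeric vector or list `(E, I, W_EI)`.
#' @param E_delayed The excitatory activity `E(t - eps)`.
#' @param W_E Self-coupling weight (global coupling of the network it
#'   stands for).
#' @param eps Delay (recorded for the caller; the delayed value itself
#'   arrives via `E_delayed`).
#' @param node A [node_params()] bundle.
#' @return Numeric vector `(dE, dI, dW_EI)`.
#' @export
single_node_rhs <- function(t, state, E_delayed, W_E, eps = 0,
                            node = node_params()) {
  if (is.list(state)) state <- c(state$E, state$I, state$W_EI)
  stopifnot(length(state) == 3, length(E_delayed) == 1)
  spec <- network_spec(matrix(W_E, 1, 1), eps = eps, node = node)
  d <- network_rhs(t, list(E = state[1], I = state[2], W_EI = state[3]),
                   matrix(E_delayed, 1, 1), spec)
  c(d$dE, d$dI, d$dW_EI)
}
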