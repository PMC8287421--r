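#' Node parameters for the homeostatic Wilson-Cowan model
#'
#' Bundles the per-node constants: target excitatory activity `p`, sigmoid
#' steepness `a`, excitatory time constant `tau1`, homeostatic plasticity
#' time constant `tau2`, and the fixed excitatory-to-inhibitory weight
#' `W_IE`. The defaults are the baseline used throughout the package's
#' analyses. All times are in units of the inhibitory time constant.
#'
#' @param p Target excitatory activity, in (0, 1). The homeostatic weight
#'   drives the excitatory population toward this level.
#' @param a Sigmoid steepness of the transfer function, `> 0`.
#' @param tau1 Excitatory population time constant, `> 0`.
#' @param tau2 Homeostatic plasticity time constant, `> 0` (slow compared
#'   with `tau1`).
#' @param W_IE Excitatory-to-inhibitory coupling weight, `> 0`.
#'
#' @return An object of class `wc_node`: a named list of the five
#'   parameters.
#' @examples
#' node_params()            # baseline bundle
#' node_params(W_IE = 1.2)  # override one constant
#' @export
node_params <- function(p = 0.2, a = 5, tau1 = 1, tau2 = 5, W_IE = 1) {
  vals <- c(p = p, a = a, tau1 = tau1, tau2 = tau2, W_IE = W_IE)
  if (any(!is.finite(vals))) stop("all node parameters must be finite", call. = FALSE)
  if (p <= 0 || p >= 1) stop("`p` must lie strictly inside (0, 1)", call. = FALSE)
  if (any(vals[c("a", "tau1", "tau2", "W_IE")] <= 0))
    stop("`a`, `tau1`, `tau2`, `W_IE` must all be positive", call. = FALSE)
  structure(list(p = p, a = a, tau1 = tau1, tau2 = tau2, W_IE = W_IE),
            class = "wc_node")
}

#' @export
print.wc_node <- function(x, ...) {
  cat("<wc_node> p =", x$p, " a =", x$a, " tau1 =", x$tau1,
      " tau2 =", x$tau2, " W_IE =", x$W_IE, "\n")
  invisible(x)
}

#' Equilibrium of the single self-coupled node
#'
#' The homeostatic node has the closed-form equilibrium
#' `E = p`, `I = phi(W_IE * p)`, and
#' `W_EI = (W_E * p - phi_inv(p)) / phi(W_IE * p)`:
#' the inhibitory weight settles at exactly the value that cancels the
#' recurrent excitatory drive down to the input that sustains activity `p`.
#' Because every node of a row-normalized network sees the same total
#' input, this is also the network equilibrium with all nodes identical.
#'
#' @param W_E Global coupling strength (row sum of the excitatory weight
#'   matrix), `> 0`.
#' @param node A [node_params()] bundle.
#' @return An object of class `wc_equilibrium`: list with elements `E`,
#'   `I`, `W_EI`.
#' @examples
#' equilibrium(2.115)
#' @export
equilibrium <- function(W_E, node = node_params()) {
  stopifnot(inherits(node, "wc_node"), is.numeric(W_E), W_E > 0)
  I_bar <- phi(node$W_IE * node$p, node$a)
  structure(
    list(E = node$p, I = I_bar,
         W_EI = (W_E * node$p - phi_inv(node$p, node$a)) / I_bar),
    class = "wc_equilibrium")
}

#' @export
print.wc_equilibrium <- function(x, ...) {
  cat(sprintf("<wc_equilibrium> E = %.6f  I = %.6f  W_EI = %.6f\n",
              x$E, x$I, x$W_EI))
  invisible(x)
}

#' Read and write parameter bundles as flat key-value files
#'
#' Parameter bundles are serialized as flat YAML with keys named after the
#' model symbols (`p`, `a`, `tau1`, `tau2`, `W_IE`, and optionally `W_E`
#' and `eps`), so runs are reproducible from a plain-text config.
#'
#' @param node A [node_params()] bundle.
#' @param path File path.
#' @param W_E,eps Optional global coupling and delay to record alongside
#'   the node constants.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a list with elements `node` (a `wc_node`) and any extra keys
#'   (`W_E`, `eps`) present in the file.
#' @export
write_params <- function(node, path, W_E = NULL, eps = NULL) {
  stopifnot(inherits(node, "wc_node"))
  x <- unclass(node)
  if (!is.null(W_E)) x$W_E <- W_E
  if (!is.null(eps)) x$eps <- eps
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  need <- c("p", "a", "tau1", "tau2", "W_IE")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("config is missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  node <- node_params(p = x$p, a = x$a, tau1 = x$tau1, tau2 = x$tau2,
                      W_IE = x$W_IE)
  out <- list(node = node)
  for (k in setdiff(names(x), need)) out[[k]] <- x[[k]]
  out
}
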