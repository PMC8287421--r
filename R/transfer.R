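#' Logistic transfer function and its inverse and derivative
#'
#' The sigmoidal transfer function maps net synaptic input to the active
#' proportion of a neural population, `phi(x) = 1 / (1 + exp(-a x))`.
#' `phi_inv()` is its inverse on (0, 1) and `phi_prime()` its derivative
#' `a * phi(x) * (1 - phi(x))`, the gain entering every linearization.
#'
#' @param x Net input (any finite real; vectorized).
#' @param y Activity level strictly inside (0, 1) (vectorized).
#' @param a Sigmoid steepness, `a > 0`.
#'
#' @return A numeric vector: activities in (0, 1) for `phi()`, net inputs
#'   for `phi_inv()`, positive gains for `phi_prime()`.
#'
#' @examples
#' phi(0, a = 5)              # 0.5 at the inflection
#' phi_inv(0.2, a = 5)        # -log(4)/5
#' phi_prime(0, a = 5)        # a/4
#' @export
phi <- function(x, a = 5) {
  stopifnot(is.numeric(x), is.numeric(a))
  if (any(!is.finite(x))) stop("`x` must be finite", call. = FALSE)
  if (any(a <= 0)) stop("`a` must be positive", call. = FALSE)
  1 / (1 + exp(-a * x))
}

#' @rdname phi
#' @export
phi_inv <- function(y, a = 5) {
  stopifnot(is.numeric(y))
  if (any(a <= 0)) stop("`a` must be positive", call. = FALSE)
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
    stop("`y` must lie strictly inside (0, 1)", call. = FALSE)
  -log(1 / y - 1) / a
}

#' @rdname phi
#' @export
phi_prime <- function(x, a = 5) {
  f <- phi(x, a)
  a * f * (1 - f)
}

#' Convert a physical conduction delay to model units
#'
#' Model time is measured in units of the inhibitory population time
#' constant, so a conduction delay of `T_ms` milliseconds corresponds to a
#' dimensionless delay `T_ms / tau_I_ms`. Cortical conduction delays of
#' 1--14 ms against an inhibitory time constant of 20 ms give delays in
#' the range 0.05--0.7.
#'
#' @param T_ms Physical conduction delay in milliseconds, `> 0`.
#' @param tau_I_ms Inhibitory time constant in milliseconds, `> 0`.
#' @return The dimensionless delay `T_ms / tau_I_ms`.
#' @examples
#' scale_delay(14, 20) # 0.7
#' @export
scale_delay <- function(T_ms, tau_I_ms = 20) {
  stopifnot(is.numeric(T_ms), is.numeric(tau_I_ms))
  if (any(!is.finite(T_ms)) || any(T_ms <= 0))
    stop("`T_ms` must be positive and finite", call. = FALSE)
  if (any(!is.finite(tau_I_ms)) || any(tau_I_ms <= 0))
    stop("`tau_I_ms` must be positive and finite", call. = FALSE)
  T_ms / tau_I_ms
}
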