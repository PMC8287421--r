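#' Constant history for a delay differential system
#'
#' Initial data for a DDE must cover the interval `[-max(lags), 0]`. The
#' common case is a constant history; an arbitrary function of time is
#' also accepted wherever a history is expected.
#'
#' @param state Numeric state vector held constant over the history span.
#' @return A function `h(t)` returning `state` for any `t <= 0`.
#' @export
constant_history <- function(state) {
  stopifnot(is.numeric(state), all(is.finite(state)))
  force(state)
  function(t) state
}

# Snap the step so the smallest positive lag is an integer number of steps
# (method-of-steps alignment: propagated derivative discontinuities then
# fall on grid points for the leading lag).
align_step <- function(step, lags) {
  pos <- lags[lags > 0]
  if (!length(pos)) return(step)
  lmin <- min(pos)
  step <- min(step, lmin / 4)
  lmin / ceiling(lmin / step - 1e-9)
}

#' Integrate a delay differential system with constant lags
#'
#' A fixed-step classical Runge-Kutta (4th order) scheme with cubic
#' Hermite dense output: states and derivatives are stored at every grid
#' point, and delayed values at stage times are interpolated from the
#' completed part of the solution, which is valid because the step never
#' exceeds the smallest positive lag. With an empty lag set the scheme
#' reduces to standard RK4. The step is aligned so that the smallest lag
#' is an integer multiple of the step.
#'
#' This is the reference, pure-R integrator used for arbitrary systems
#' and cross-checks; the production Wilson-Cowan paths
#' ([integrate_network()], [integrate_single_node()]) use the identical
#' scheme in compiled code.
#'
#' @param rhs Function `rhs(t, y, lookup)` returning `dy/dt`; `lookup(s)`
#'   returns the full state vector at any earlier time `s <= t` (history
#'   for `s <= t0`, interpolated solution afterwards).
#' @param lags Numeric vector of nonnegative constant lags (may be empty).
#' @param history A [constant_history()] function (or any `h(t)`), or a
#'   numeric vector treated as a constant history.
#' @param t_span Length-2 numeric, `c(t0, t_end)`.
#' @param step Step size; capped at a quarter of the smallest positive lag.
#' @return A `wc_trajectory`; see [trajectory_at()] and
#'   [as_tibble.wc_trajectory()].
#' @examples
#' # x'(t) = -x(t - 1) from constant history 1: x(t) = 1 - t on [0, 1]
#' tr <- integrate_dde(function(t, y, lookup) -lookup(t - 1),
#'                     lags = 1, history = 1, t_span = c(0, 2), step = 0.05)
#' trajectory_at(tr, 1) # ~0
#' @export
integrate_dde <- function(rhs, lags, history, t_span, step = 0.01) {
  stopifnot(is.function(rhs), is.numeric(t_span), length(t_span) == 2)
  lags <- as.numeric(lags)
  if (any(!is.finite(lags)) || any(lags < 0))
    stop("lags must be nonnegative and finite", call. = FALSE)
  if (is.numeric(history)) history <- constant_history(history)
  stopifnot(is.function(history))
  t0 <- t_span[1]; t_end <- t_span[2]
  stopifnot(t_end > t0)
  h <- align_step(step, lags)
  n <- ceiling((t_end - t0) / h - 1e-9)
  h <- (t_end - t0) / n # land exactly on t_end

  y0 <- history(t0)
  d <- length(y0)
  yy <- matrix(NA_real_, n + 1, d)
  ff <- matrix(NA_real_, n + 1, d)
  tt <- t0 + h * (0:n)
  yy[1, ] <- y0

  # dense lookup over [history, completed solution]; `upto` marks the last
  # completed grid index usable by Hermite interpolation.
  upto <- 1L
  lookup <- function(s) {
    if (s <= t0 + 1e-14) return(history(s))
    u <- (s - t0) / h
    i0 <- floor(u + 1e-9)
    if (i0 >= upto) i0 <- upto - 1L
    th <- u - i0
    th <- min(max(th, 0), 1)
    i <- i0 + 1L
    th2 <- th * th; th3 <- th2 * th
    (2 * th3 - 3 * th2 + 1) * yy[i, ] + (th3 - 2 * th2 + th) * h * ff[i, ] +
      (-2 * th3 + 3 * th2) * yy[i + 1L, ] + (th3 - th2) * h * ff[i + 1L, ]
  }

  for (i in 1:(n + 1)) {
    t <- tt[i]
    y <- yy[i, ]
    k1 <- rhs(t, y, lookup)
    ff[i, ] <- k1
    upto <- i
    if (i == n + 1) break
    k2 <- rhs(t + h / 2, y + h / 2 * k1, lookup)
    k3 <- rhs(t + h / 2, y + h / 2 * k2, lookup)
    k4 <- rhs(t + h, y + h * k3, lookup)
    ynew <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(ynew)))
      stop(sprintf("state became non-finite at t = %g", t + h), call. = FALSE)
    yy[i + 1, ] <- ynew
  }

  new_trajectory(tt, yy, ff, vars = paste0("y", seq_len(d)))
}

new_trajectory <- function(t, y, f, vars) {
  colnames(y) <- vars
  colnames(f) <- vars
  structure(list(t = t, y = y, f = f, vars = vars,
                 step = if (length(t) > 1) t[2] - t[1] else NA_real_),
            class = "wc_trajectory")
}

#' Evaluate a trajectory at arbitrary times
#'
#' Cubic Hermite interpolation from the stored states and derivatives; at
#' grid points the stored states are returned exactly.
#'
#' @param traj A `wc_trajectory`.
#' @param s Numeric vector of query times inside the trajectory span.
#' @param vars Optional character vector of state names to return.
#' @return A matrix (`length(s)` rows) of interpolated states.
#' @export
trajectory_at <- function(traj, s, vars = NULL) {
  stopifnot(inherits(traj, "wc_trajectory"))
  tt <- traj$t
  if (any(s < tt[1] - 1e-12) || any(s > tt[length(tt)] + 1e-12))
    stop("query time outside the trajectory span", call. = FALSE)
  h <- traj$step
  cols <- if (is.null(vars)) seq_along(traj$vars) else match(vars, traj$vars)
  if (anyNA(cols)) stop("unknown state variable requested", call. = FALSE)
  out <- matrix(NA_real_, length(s), length(cols))
  u <- (s - tt[1]) / h
  i0 <- pmin(pmax(floor(u + 1e-9), 0), length(tt) - 2L)
  th <- pmin(pmax(u - i0, 0), 1)
  exact <- abs(th) < 1e-12
  th2 <- th * th; th3 <- th2 * th
  a0 <- 2 * th3 - 3 * th2 + 1; a1 <- th3 - 2 * th2 + th
  b0 <- -2 * th3 + 3 * th2; b1 <- th3 - th2
  for (j in seq_along(cols)) {
    c0 <- traj$y[, cols[j]]; d0 <- traj$f[, cols[j]]
    v <- a0 * c0[i0 + 1L] + a1 * h * d0[i0 + 1L] +
      b0 * c0[i0 + 2L] + b1 * h * d0[i0 + 2L]
    v[exact] <- c0[i0 + 1L][exact]
    out[, j] <- v
  }
  colnames(out) <- traj$vars[cols]
  out
}

#' @export
print.wc_trajectory <- function(x, ...) {
  cat(sprintf("<wc_trajectory> %d states over t = [%g, %g] (%d points)\n",
              ncol(x$y), x$t[1], x$t[length(x$t)], length(x$t)))
  invisible(x)
}

#' Convert a trajectory to a tibble
#'
#' @param x A `wc_trajectory`.
#' @param ... Unused.
#' @return A tibble with a `t` column followed by one column per state.
#' @importFrom tibble as_tibble
#' @export
as_tibble.wc_trajectory <- function(x, ...) {
  tibble::as_tibble(cbind(data.frame(t = x$t), as.data.frame(x$y)))
}

#' Export a trajectory as delimited text
#'
#' @param traj A `wc_trajectory`.
#' @param path Output CSV path (`t` column, then state columns).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as_tibble(traj), path, row.names = FALSE)
  invisible(path)
}
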