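test_that("network started at the equilibrium stays there", {
  net <- network_spec(ring_unidirectional(3, 2.115), eps = 0.1,
                      node = baseline)
  tr <- integrate_network(net, t_end = 20, record_every = 0.1)
  eq <- equilibrium(2.115, baseline)
  expect_lt(max(abs(tr$y[, 1:3] - eq$E)), 1e-12)
  expect_lt(max(abs(tr$y[, 7:9] - eq$W_EI)), 1e-12)
})

test_that("homogeneous delays and identical histories keep nodes identical", {
  net <- network_spec(ring_unidirectional(2, 2.25), eps = 0.1,
                      node = baseline)
  eq <- equilibrium(2.25, baseline)
  tr <- integrate_network(net,
                          history = list(E = rep(eq$E + 0.05, 2),
                                         I = rep(eq$I, 2),
                                         W_EI = rep(eq$W_EI, 2)),
                          t_end = 200, record_every = 0.05)
  expect_lt(max(abs(tr$y[, "E1"] - tr$y[, "E2"])), 1e-8)
  expect_lt(max(abs(tr$y[, "I1"] - tr$y[, "I2"])), 1e-8)
})

test_that("compiled single-node path matches the pure-R DDE integrator", {
  W_E <- 2.25; eps <- 0.2
  eq <- equilibrium(W_E, baseline)
  h0 <- c(eq$E + 0.05, eq$I, eq$W_EI)
  rhs <- function(t, y, lookup)
    single_node_rhs(t, y, E_delayed = lookup(t - eps)[1], W_E = W_E,
                    eps = eps, node = baseline)
  ref <- integrate_dde(rhs, lags = eps, history = h0, t_span = c(0, 30),
                       step = 0.01)
  got <- integrate_single_node(W_E, eps, baseline, history = h0, t_end = 30,
                               record_every = 0.01)
  at <- seq(0, 30, by = 0.5)
  expect_equal(unname(trajectory_at(got, at)), unname(trajectory_at(ref, at)),
               tolerance = 1e-10)
})

test_that("activities stay inside the transfer function's range", {
  net <- network_spec(random_row_normalized(5, 2.4, seed = 3), eps = 0.15,
                      node = baseline)
  eq <- equilibrium(2.4, baseline)
  tr <- integrate_network(net,
                          history = list(E = rep(0.9, 5), I = rep(0.1, 5),
                                         W_EI = rep(eq$W_EI, 5)),
                          t_end = 300, record_from = 1, record_every = 0.1)
  E <- tr$y[, 1:5]; I <- tr$y[, 6:10]
  expect_true(all(E > 0 & E < 1))
  expect_true(all(I > 0 & I < 1))
})

test_that("heterogeneous lags are honored without grid rounding", {
  # two nodes, distinct irrational-ish lags; compare against the pure-R
  # integrator fed the same per-pair lookups
  W <- matrix(c(0, 2, 2, 0), 2, 2)
  epsm <- matrix(c(0, 0.13, 0.071, 0), 2, 2)
  net <- network_spec(W, eps = epsm, node = baseline)
  eq <- equilibrium(2, baseline)
  h0 <- c(eq$E + 0.03, eq$E - 0.02, eq$I, eq$I, eq$W_EI, eq$W_EI)
  rhs <- function(t, y, lookup) {
    dE <- numeric(2); dI <- numeric(2); dW <- numeric(2)
    for (k in 1:2) {
      j <- 3 - k
      Ej <- lookup(t - epsm[k, j])[j]
      dE[k] <- (-y[k] + phi(2 * Ej - y[4 + k] * y[2 + k], 5)) / 1
      dI[k] <- -y[2 + k] + phi(y[k], 5)
      dW[k] <- y[2 + k] * (y[k] - 0.2) / 5
    }
    c(dE, dI, dW)
  }
  ref <- integrate_dde(rhs, lags = c(0.13, 0.071),
                       history = h0, t_span = c(0, 20), step = 0.005)
  got <- integrate_network(net,
                           history = list(E = h0[1:2], I = h0[3:4],
                                          W_EI = h0[5:6]),
                           t_end = 20, step = 0.005, record_every = 0.1)
  at <- seq(1, 20, by = 1)
  expect_equal(unname(trajectory_at(got, at, vars = c("E1", "E2"))),
               unname(trajectory_at(ref, at)[, 1:2]), tolerance = 1e-7)
})

test_that("trajectories export and tidy cleanly", {
  tr <- integrate_single_node(2.05, 0.1, baseline, t_end = 5,
                              record_every = 0.1)
  tb <- as_tibble(tr)
  expect_named(tb, c("t", "E", "I", "W_EI"))
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- utils::read.csv(path)
  expect_equal(back$E, unname(tr$y[, "E"]), tolerance = 1e-12)
})
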