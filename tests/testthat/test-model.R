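test_that("node parameter bundle validates its domain", {
  nd <- node_params()
  expect_s3_class(nd, "wc_node")
  expect_equal(unlist(nd), c(p = 0.2, a = 5, tau1 = 1, tau2 = 5, W_IE = 1))
  expect_error(node_params(p = 0), "inside")
  expect_error(node_params(p = 1.3), "inside")
  expect_error(node_params(tau2 = -1), "positive")
})

test_that("equilibrium formula satisfies the closed form and kills the flow", {
  eq <- equilibrium(2.115, baseline)
  expect_equal(eq$E, 0.2)
  expect_equal(round(eq$I, 6), 0.731059)
  expect_equal(eq$W_EI, 0.9578698, tolerance = 1e-7)
  expect_equal(eq$W_EI, (2.115 * 0.2 + log(4) / 5) / phi(0.2, 5),
               tolerance = 1e-12)
  for (W_E in c(0.5, 2.05, 3.7)) {
    eq <- equilibrium(W_E, baseline)
    d <- single_node_rhs(0, c(eq$E, eq$I, eq$W_EI), E_delayed = eq$E,
                         W_E = W_E, eps = 0.3, node = baseline)
    expect_lt(max(abs(d)), 1e-10)
  }
})

test_that("network_spec enforces row normalization and delay shape", {
  W <- ring_unidirectional(4, 2.115)
  net <- network_spec(W, eps = 0.1)
  expect_equal(net$W_E, 2.115)
  expect_equal(dim(net$eps), c(4, 4))
  Wbad <- W; Wbad[1, 2] <- Wbad[1, 2] + 1e-6
  expect_error(network_spec(Wbad), "sum")
  expect_error(network_spec(W, eps = -0.1), "nonnegative")
  expect_error(network_spec(matrix(-1, 2, 2)), "nonnegative")
})

test_that("network right-hand side matches a hand-evaluated point", {
  # N = 1, state (E, I, W_EI) = (0.3, 0.6, 1.0), delayed E = 0.25, W_E = 2
  spec <- network_spec(matrix(2, 1, 1), eps = 0.1, node = baseline)
  d <- network_rhs(0, list(E = 0.3, I = 0.6, W_EI = 1.0),
                   matrix(0.25, 1, 1), spec)
  expect_equal(d$dE, -0.3 + 1 / (1 + exp(-5 * (2 * 0.25 - 1.0 * 0.6))),
               tolerance = 1e-12)
  expect_equal(d$dI, -0.6 + 1 / (1 + exp(-5 * 0.3)), tolerance = 1e-12)
  expect_equal(d$dW_EI, 0.6 * (0.3 - 0.2) / 5, tolerance = 1e-12)
})

test_that("single-node equations are the N = 1 reduction of the network", {
  set.seed(42)
  for (i in 1:10) {
    st <- runif(3, c(0.05, 0.05, -0.5), c(0.95, 0.95, 2))
    Ed <- runif(1, 0.05, 0.95)
    W_E <- runif(1, 0.5, 3)
    d1 <- single_node_rhs(0, st, Ed, W_E, eps = 0.2, node = baseline)
    spec <- network_spec(matrix(W_E, 1, 1), eps = 0.2, node = baseline)
    d2 <- network_rhs(0, list(E = st[1], I = st[2], W_EI = st[3]),
                      matrix(Ed, 1, 1), spec)
    expect_equal(d1, c(d2$dE, d2$dI, d2$dW_EI), tolerance = 1e-15)
  }
})

test_that("the identical-node equilibrium is a fixed point for any topology", {
  set.seed(9)
  for (N in c(3, 6)) {
    W <- random_row_normalized(N, W_E = 2.4, seed = N)
    eps <- matrix(runif(N * N, 0, 0.3), N, N)
    spec <- network_spec(W, eps = eps, node = baseline)
    eq <- equilibrium(2.4, baseline)
    d <- network_rhs(0, list(E = rep(eq$E, N), I = rep(eq$I, N),
                             W_EI = rep(eq$W_EI, N)),
                     matrix(eq$E, N, N), spec)
    expect_lt(max(abs(unlist(d))), 1e-12)
  }
})

test_that("parameter bundles round-trip through the key-value config", {
  path <- tempfile(fileext = ".yaml")
  write_params(node_params(W_IE = 1.4), path, W_E = 2.05, eps = 0.1)
  got <- read_params(path)
  expect_equal(got$node$W_IE, 1.4)
  expect_equal(got$W_E, 2.05)
  expect_equal(got$eps, 0.1)
  expect_error(read_params({
    p2 <- tempfile(fileext = ".yaml"); yaml::write_yaml(list(p = 0.2), p2); p2
  }), "missing keys")
})
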