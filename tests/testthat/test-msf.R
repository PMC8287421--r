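test_that("the delay line reproduces a delayed sinusoid and a constant", {
  # drive the driven cells x_2..x_m with head x_1 = sin(w t) and compare
  # the tail with the delayed signal; the chain's effective delay
  # converges as m grows
  tail_error <- function(m, eps = 0.2, w = 1) {
    ch <- discretize_delay_line(eps, m)
    h <- eps / (2 * m)
    n <- round(60 / h)
    x <- numeric(m - 1)
    f <- function(t, x) ch$A %*% x + ch$b * sin(w * t)
    t <- 0
    for (i in 1:n) {
      k1 <- f(t, x); k2 <- f(t + h / 2, x + h / 2 * k1)
      k3 <- f(t + h / 2, x + h / 2 * k2); k4 <- f(t + h, x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    abs(x[m - 1] - sin(w * (t - eps)))
  }
  errs <- vapply(c(5, 10, 20, 40), tail_error, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[4], 5e-3)

  # constant input: every cell settles to the input value
  ch <- discretize_delay_line(0.2, 10)
  fixed <- solve(ch$A, -ch$b * 0.7)
  expect_equal(fixed, rep(0.7, 9), tolerance = 1e-10)
  expect_error(discretize_delay_line(0, 10), "eps > 0")
  expect_error(discretize_delay_line(0.1, 1), "at least 2")
})

test_that("variational coefficients freeze to the known equilibrium gains", {
  eq <- equilibrium(2.115, baseline)
  co <- msf_coefficients(E_lag = eq$E, I = eq$I, W_EI = eq$W_EI, E = eq$E,
                         W_E = 2.115, node = baseline)
  expect_equal(co$M1, 0.8, tolerance = 1e-12) # a p (1 - p)
  expect_equal(co$M2, 0.9830597, tolerance = 1e-7) # W_IE phi'(W_IE p)
  expect_gt(co$M1, 0); expect_gt(co$M2, 0)
})

test_that("variational right-hand side is linear and structurally correct", {
  eq <- equilibrium(2.115, baseline)
  sync <- function(s) c(eq$E, eq$I, eq$W_EI)
  v <- c(0.3 + 0.1i, -0.2, 0.5i)
  d1 <- variational_rhs(0, v, eta_x_lag = v[1], r_hat = 0.6, sync = sync,
                        W_E = 2.115, eps = 0.1, node = baseline)
  d2 <- variational_rhs(0, 2 * v, eta_x_lag = 2 * v[1], r_hat = 0.6,
                        sync = sync, W_E = 2.115, eps = 0.1, node = baseline)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # with r_hat = 0 and frozen coefficients this is the equilibrium
  # linearization without the delayed term
  d0 <- variational_rhs(0, c(1, 0, 0), eta_x_lag = 1, r_hat = 0,
                        sync = sync, W_E = 2.115, eps = 0, node = baseline)
  J <- wcdelay:::variational_jacobian(2.115, baseline, r_hat = 0)
  expect_equal(Re(d0), as.vector(J %*% c(1, 0, 0)), tolerance = 1e-12)
})

test_that("chain Lyapunov exponents match characteristic roots at the equilibrium", {
  # below the Hopf point the synchronous solution is the stable
  # equilibrium, so the exponent must equal the rightmost root's real part
  pts <- c(0.9, 0.5 + 0.0i, -0.7, 0.3 + 0.4i, 0.8i)
  for (W_E in c(1.6, 1.8)) {
    for (r in pts) {
      lam <- max_lyapunov(r * W_E, W_E, eps = 0.1, node = baseline,
                          cfg = test_lyap)$lambda
      root <- Re(rightmost_root(W_E, eps = 0.1, node = baseline,
                                r_hat = r * W_E))
      expect_lt(abs(lam - root), 1e-2)
    }
  }
})

test_that("the Perron direction is neutral on the limit cycle", {
  for (W_E in c(2.115, 2.25)) {
    l <- max_lyapunov(W_E, W_E, eps = 0.1, node = baseline, cfg = test_lyap)
    expect_lt(abs(l$lambda), 0.01)
  }
})

test_that("exponents respect conjugation symmetry and local continuity", {
  r <- (0.4 + 0.5i) * 2.115
  up <- max_lyapunov(r, 2.115, 0.1, baseline, cfg = test_lyap)$lambda
  dn <- max_lyapunov(Conj(r), 2.115, 0.1, baseline, cfg = test_lyap)$lambda
  expect_lt(abs(up - dn), 5e-3)
  near <- max_lyapunov(r + 0.01, 2.115, 0.1, baseline, cfg = test_lyap)$lambda
  expect_lt(abs(up - near), 0.05)
})

test_that("direct linear-DDE integration agrees with the chain in sign", {
  pts <- half_disk_points(8, seed = 21)
  n_checked <- 0
  for (r in pts) {
    lam <- max_lyapunov(r * 2.115, 2.115, 0.1, baseline, cfg = test_lyap)
    g <- direct_dde_growth(r * 2.115, 2.115, 0.1, baseline, cfg = test_lyap)
    if (abs(lam$lambda) < 1e-3 || g$classification == "marginal") next
    expect_equal(sign(lam$lambda),
                 ifelse(g$classification == "grew", 1, -1))
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 5)
  # a perturbation at r_hat = 0 below the Hopf point must decay
  expect_equal(direct_dde_growth(0, 1.8, 0.1, baseline,
                                 cfg = fast_lyap)$classification, "decayed")
})

test_that("MSF region is conjugate-symmetric and contains the origin", {
  reg <- msf_region(2.05, eps = 0.1, node = baseline, resolution = 5,
                    lim = 1.0, cfg = fast_lyap)
  tb <- tibble::as_tibble(reg)
  at0 <- tb$lambda[abs(tb$re) < 1e-12 & abs(tb$im) < 1e-12]
  expect_lt(at0, 0)
  up <- tb[tb$im > 0, ]
  dn <- tb[tb$im < 0, ]
  dn <- dn[order(dn$re, dn$im), ]
  up <- up[order(up$re, -up$im), ]
  expect_equal(up$lambda, dn$lambda, tolerance = 1e-12)
  expect_s3_class(glance(reg), "tbl_df")
})

test_that("synchronization verdicts follow the transverse exponents", {
  W7 <- ring_unidirectional(7, 2.115)
  pred7 <- predict_synchronization(W7, eps = 0.1, node = baseline,
                                   cfg = test_lyap)
  expect_equal(attr(pred7, "verdict"), "stable")
  expect_equal(sum(pred7$role == "perron"), 1L)
  expect_true(all(pred7$lambda[pred7$role == "transverse"] < 0))
  W8 <- ring_unidirectional(8, 2.115)
  pred8 <- predict_synchronization(W8, eps = 0.1, node = baseline,
                                   cfg = test_lyap)
  expect_equal(attr(pred8, "verdict"), "unstable")
  expect_error(predict_synchronization(matrix(c(1, 0, 0, 2), 2, 2)),
               "row-normalized")
  gl <- glance(pred8)
  expect_gt(gl$max_transverse_lambda, 0)
})

test_that("synchronous trajectory settles below Hopf and cycles above", {
  low <- synchronous_trajectory(1.8, 0.1, baseline, transient = 300,
                                record = 100, record_every = 0.05)
  expect_lt(max(low$y[, "E"]) - min(low$y[, "E"]), 1e-3)
  hi <- synchronous_trajectory(2.115, 0.1, baseline, transient = 300,
                               record = 100, record_every = 0.05)
  expect_gt(max(hi$y[, "E"]) - min(hi$y[, "E"]), 0.05)
})
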