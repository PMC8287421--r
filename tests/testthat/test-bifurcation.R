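test_that("characteristic function vanishes at the no-delay Jacobian spectrum", {
  for (W_E in c(1.5, 2.115, 3)) {
    J <- wcdelay:::variational_jacobian(W_E, baseline)
    ev <- eigen(J, only.values = TRUE)$values
    expect_lt(max(Mod(char_fn(ev, W_E, eps = 0, node = baseline))), 1e-10)
  }
})

test_that("characteristic function has conjugate symmetry and eps-free origin", {
  set.seed(3)
  z <- complex(real = runif(100, -3, 2), imaginary = runif(100, -10, 10))
  expect_equal(char_fn(Conj(z), 2.115, 0.3, baseline),
               Conj(char_fn(z, 2.115, 0.3, baseline)), tolerance = 1e-12)
  at0 <- vapply(c(0, 0.1, 0.4, 0.7),
                function(e) Re(char_fn(0, 2.115, e, baseline)), numeric(1))
  expect_equal(diff(range(at0)), 0, tolerance = 1e-14)
})

test_that("rightmost root agrees with the explicit Jacobian when eps = 0", {
  for (W_E in c(1.8, 2.3)) {
    rr <- rightmost_root(W_E, eps = 0, node = baseline)
    ev <- eigen(wcdelay:::variational_jacobian(W_E, baseline),
                only.values = TRUE)$values
    expect_equal(Re(rr), max(Re(ev)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # transcendental path against the polynomial one at tiny delay
  rr_small <- rightmost_root(2.3, eps = 1e-8, node = baseline)
  rr_poly <- rightmost_root(2.3, eps = 0, node = baseline)
  expect_equal(Re(rr_small), Re(rr_poly), tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("Hopf point sits where the rightmost root crosses the axis", {
  hp <- hopf_point(W_IE = 1, eps = 0.1, node = baseline, validate = FALSE)
  expect_lt(Mod(char_fn(1i * hp$omega, hp$W_E_hopf, 0.1, baseline)), 1e-9)
  expect_lt(Re(rightmost_root(hp$W_E_hopf * 0.98, 0.1, baseline)), 0)
  expect_gt(Re(rightmost_root(hp$W_E_hopf * 1.02, 0.1, baseline)), 0)
  # no-delay anchor against direct bisection of the Jacobian spectrum
  hp0 <- hopf_point(W_IE = 1, eps = 0, node = baseline, validate = FALSE)
  bf <- wcdelay:::hopf_eps0_bruteforce(1, baseline)
  expect_equal(hp0$W_E_hopf, bf$W_E_hopf, tolerance = 1e-8)
  expect_gt(hp0$omega, 0)
})

test_that("simulations are sub/supercritical around the Hopf point", {
  hp <- hopf_point(W_IE = 1, eps = 0.1, node = baseline, validate = FALSE)
  eq <- equilibrium(hp$W_E_hopf * 0.95, baseline)
  below <- integrate_single_node(hp$W_E_hopf * 0.95, 0.1, baseline,
                                 t_end = 800, record_from = 700)
  expect_lt(max(abs(below$y[, "E"] - eq$E)), 1e-3)
  above <- integrate_single_node(hp$W_E_hopf * 1.05, 0.1, baseline,
                                 t_end = 800, record_from = 700)
  expect_gt(max(above$y[, "E"]) - min(above$y[, "E"]), 0.02)
})

test_that("the Hopf threshold is nondecreasing in the delay", {
  W <- vapply(c(0, 0.1, 0.3, 0.5), function(e)
    hopf_point(W_IE = 1, eps = e, node = baseline,
               validate = FALSE)$W_E_hopf, numeric(1))
  expect_true(all(diff(W) > 0))
})

test_that("Hopf curves are continuous in W_IE with positive frequency", {
  crv <- hopf_curve(seq(0.8, 1.2, by = 0.1), eps = 0.1, node = baseline)
  expect_equal(nrow(crv), 5L)
  expect_true(all(abs(diff(crv$W_E_hopf)) < 0.5))
  expect_true(all(crv$omega > 0 & is.finite(crv$omega)))
})

test_that("below the Hopf point the orbit diagram is empty or equilibrium-valued", {
  od <- orbit_diagram(c(1.6, 1.8), eps = 0.1, node = baseline,
                      transient = 400, record = 400)
  tb <- tibble::as_tibble(od)
  for (w in unique(tb$W_E)) {
    rows <- tb[tb$W_E == w, ]
    expect_lte(rows$n_clusters[1], 1)
    if (rows$n_clusters[1] == 1)
      expect_lt(abs(rows$peak[1] - 0.2), 5e-3)
  }
})

test_that("period-doubling detection reads cluster-count transitions", {
  fake <- tibble::tibble(
    W_E = rep(c(2.0, 2.1, 2.2, 2.3), times = c(1, 1, 2, 4)),
    peak = c(0.3, 0.31, 0.30, 0.33, 0.28, 0.30, 0.32, 0.35),
    n_in_cluster = 1L,
    n_clusters = rep(c(1L, 1L, 2L, 4L), times = c(1, 1, 2, 4)),
    diverged = FALSE)
  class(fake) <- c("wc_orbit_diagram", class(fake))
  hits <- detect_period_doubling(fake)
  expect_equal(hits$W_E_lo, c(2.1, 2.2))
  expect_equal(hits$to, c(2L, 4L))
  flat <- fake[fake$n_clusters == 1, ]
  class(flat) <- c("wc_orbit_diagram", class(flat))
  expect_equal(nrow(detect_period_doubling(flat)), 0L)
})
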