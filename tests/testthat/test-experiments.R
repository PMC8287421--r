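test_that("identical histories with homogeneous delays read as synchronized", {
  spec <- network_spec(ring_unidirectional(4, 2.115), eps = 0.1,
                       node = baseline)
  met <- simulate_and_measure(spec, perturb_scale = 0, t_end = 300)
  expect_lt(met$sync_error, 1e-8)
  expect_true(met$is_synchronized)
})

test_that("attractor distance is zero on itself and amplitude-sized across regimes", {
  cyc <- integrate_single_node(2.25, 0.1, baseline, t_end = 600,
                               record_from = 400)
  expect_equal(attractor_distance(cyc, cyc), 0)
  eqtr <- integrate_single_node(1.8, 0.1, baseline, t_end = 600,
                                record_from = 400)
  amp <- max(cyc$y[, "E"]) - min(cyc$y[, "E"])
  d <- attractor_distance(eqtr, cyc)
  expect_gt(d, amp / 4)
  expect_lt(d, 2 * amp)
  expect_error(attractor_distance(cyc, cyc, window = c(0, 100)), "span")
})

test_that("a synchronized random network lands on the single node's attractor", {
  spec <- network_spec(random_row_normalized(10, 2.25, seed = 1), eps = 0.1,
                       node = baseline)
  met <- simulate_and_measure(spec, seed = 1, keep_trajectory = TRUE)
  expect_true(met$is_synchronized)
  single <- integrate_single_node(2.25, 0.1, baseline, t_end = 2000,
                                  record_from = 1600)
  expect_lt(attractor_distance(attr(met, "trajectory"), single), 0.05)
})

test_that("phase lags are near zero for a synchronized homogeneous network", {
  spec <- network_spec(random_row_normalized(6, 2.25, seed = 2), eps = 0.1,
                       node = baseline)
  met <- simulate_and_measure(spec, seed = 2, t_end = 1000,
                              keep_trajectory = TRUE)
  lags <- phase_lags(attr(met, "trajectory"))
  expect_lt(max(abs(lags)), 0.2)
})

test_that("metrics are reproducible for a fixed seed", {
  spec <- network_spec(ring_unidirectional(5, 2.05), eps = 0.1,
                       node = baseline)
  m1 <- simulate_and_measure(spec, seed = 4, t_end = 400)
  m2 <- simulate_and_measure(spec, seed = 4, t_end = 400)
  expect_identical(m1$sync_error, m2$sync_error)
  m3 <- simulate_and_measure(spec, seed = 5, t_end = 400)
  expect_false(identical(m1$sync_error, m3$sync_error))
})

test_that("the variance-free delay sample reproduces homogeneous metrics", {
  W <- ring_unidirectional(5, 2.115)
  dl <- heterogeneous_delays(W, 0.1, alpha = 1e9, beta = 1e9, seed = 1)
  expect_lt(max(abs(dl$eps[W > 0] - 0.1)), 2e-5)
  hom <- simulate_and_measure(network_spec(W, eps = 0.1, node = baseline),
                              seed = 1, t_end = 600)
  het <- simulate_and_measure(network_spec(W, eps = dl, node = baseline),
                              seed = 1, t_end = 600)
  expect_equal(het$sync_error, hom$sync_error, tolerance = 1e-3)
  expect_equal(het$is_synchronized, hom$is_synchronized)
})

test_that("experiment reports carry manifests and reproducible CSV output", {
  cfg <- list(eps_hopf = c(0, 0.1), eps_orbit = c(0.1),
              W_E_grid = seq(2.0, 2.3, by = 0.1), transient = 300,
              record = 300)
  out1 <- tempfile(); out2 <- tempfile()
  r1 <- run_experiment("single_node", cfg, out_dir = out1)
  r2 <- run_experiment("single_node", cfg, out_dir = out2)
  expect_s3_class(r1$results$hopf, "tbl_df")
  expect_true(all(file.exists(r1$files)))
  csv1 <- r1$files[grepl("hopf", r1$files)]
  csv2 <- r2$files[grepl("hopf", r2$files)]
  expect_identical(readLines(csv1), readLines(csv2))
  expect_true(any(grepl("manifest", r1$files)))
  man <- yaml::read_yaml(r1$files[grepl("manifest", r1$files)])
  expect_equal(man$transient, 300)
})
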