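test_that("unidirectional ring spectra are the roots of unity", {
  sp <- spectrum(ring_unidirectional(4, 2.115), 2.115)
  got <- sort(complex(real = sp$re_scaled, imaginary = sp$im_scaled))
  want <- sort(exp(2i * pi * (0:3) / 4))
  expect_equal(got, want, tolerance = 1e-10)
  sp8 <- spectrum(ring_unidirectional(8, 1), 1)
  z <- complex(real = sp8$re_scaled, imaginary = sp8$im_scaled)
  expect_lt(min(Mod(z - exp(1i * pi / 4))), 1e-10)
  for (N in c(1, 2, 5, 9))
    expect_equal(rowSums(ring_unidirectional(N, 2.7)), rep(2.7, N))
  expect_equal(ring_unidirectional(1, 2.115), matrix(2.115, 1, 1))
  expect_error(ring_unidirectional(0), "at least 1")
})

test_that("ring-lattice spectra are cos(2 pi k / N), purely real", {
  for (N in c(5, 15)) {
    sp <- spectrum(ring_lattice(N, 2.115), 2.115)
    expect_lt(max(abs(sp$im)), 1e-12)
    expect_equal(sort(sp$re_scaled), sort(cos(2 * pi * (0:(N - 1)) / N)),
                 tolerance = 1e-10)
  }
  sp15 <- spectrum(ring_lattice(15, 1), 1)
  expect_equal(round(sort(sp15$re_scaled, decreasing = TRUE)[2], 6),
               0.913545)
  expect_error(ring_lattice(2), "at least 3")
})

test_that("random row-normalized networks have exact row sums and Perron 1", {
  for (seed in 1:5) {
    W <- random_row_normalized(8, 2.115, seed = seed)
    expect_equal(rowSums(W), rep(2.115, 8), tolerance = 1e-12)
    expect_true(all(diag(W) == 0))
    sp <- spectrum(W, 2.115)
    expect_lt(abs(sp$mod_scaled[1] - 1), 1e-10)
    expect_true(sp$is_perron[1])
  }
  expect_identical(random_row_normalized(6, 2, seed = 7),
                   random_row_normalized(6, 2, seed = 7))
})

test_that("non-Perron eigenvalues of random networks shrink with N", {
  second_mag <- function(N) {
    vapply(1:50, function(s) {
      sp <- spectrum(random_row_normalized(N, 1, seed = s), 1)
      sort(sp$mod_scaled, decreasing = TRUE)[2]
    }, numeric(1))
  }
  expect_lt(stats::median(second_mag(24)), stats::median(second_mag(6)))
})

test_that("heterogeneous delays hit the target mean exactly and reproduce", {
  W <- ring_unidirectional(7, 2.115)
  d <- heterogeneous_delays(W, mean_eps = 0.1, seed = 5)
  expect_equal(mean(d$eps[W > 0]), 0.1, tolerance = 1e-14)
  expect_true(all(d$eps[W > 0] > 0))
  expect_true(all(d$eps[W == 0] == 0))
  d2 <- heterogeneous_delays(W, mean_eps = 0.1, seed = 5)
  expect_identical(d$eps, d2$eps)
  # concentration: large equal shapes approach the homogeneous limit
  dh <- heterogeneous_delays(W, 0.1, alpha = 5e5, beta = 5e5, seed = 2)
  expect_lt(max(abs(dh$eps[W > 0] - 0.1)), 1e-3)
  expect_error(heterogeneous_delays(W, -1), "positive")
  expect_error(heterogeneous_delays(matrix(0, 2, 2), 0.1), "edges")
})

test_that("spectrum orders deterministically and flags the Perron direction", {
  W <- ring_lattice(6, 2)
  sp <- spectrum(W)
  expect_true(all(diff(sp$re) <= 1e-12))
  expect_equal(sum(sp$is_perron), 1L)
  expect_equal(sp$re_scaled[sp$is_perron], 1, tolerance = 1e-12)
  expect_error(spectrum(matrix(1, 2, 3)), "square")
  expect_error(spectrum(matrix(c(1, 0, 0, 2), 2, 2)), "row")
  expect_silent(spectrum(matrix(c(1, 0, 0, 2), 2, 2), W_E = 2))
})

test_that("matrices and spectra round-trip through delimited text", {
  W <- random_row_normalized(5, 2.115, seed = 1)
  path <- tempfile(fileext = ".txt")
  write_matrix(W, path)
  back <- read_matrix(path)
  expect_equal(unname(back), W, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(attr(back, "row_sums"), rep(2.115, 5), tolerance = 1e-10)
  neg <- tempfile(fileext = ".txt")
  write.table(matrix(c(1, -1, 0, 1), 2, 2), neg, row.names = FALSE,
              col.names = FALSE)
  expect_error(read_matrix(neg), "nonnegative")
  sp <- spectrum(W, 2.115)
  sp_path <- tempfile(fileext = ".csv")
  write_spectrum(sp, sp_path)
  expect_named(utils::read.csv(sp_path),
               c("re", "im", "re_scaled", "im_scaled"))
})
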