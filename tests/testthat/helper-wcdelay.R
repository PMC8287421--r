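# Shared fixtures for the test suite.

baseline <- node_params() # p = 0.2, a = 5, tau1 = 1, tau2 = 5, W_IE = 1

# Lyapunov settings for tests: fixed averaging window (no adaptive
# extension) keeps runtimes predictable; 2000 time units is the package
# default and converges well inside the 1e-2 tolerances asserted below.
test_lyap <- lyap_config(t_avg = 2000, extend = FALSE)

# Short-averaging variant for coarse structural checks.
fast_lyap <- lyap_config(transient = 300, t_avg = 600, extend = FALSE)

# Deterministic sample of complex points in the closed upper unit
# half-disk (conjugates are implied by symmetry).
half_disk_points <- function(n, seed = 11) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  complex(modulus = sqrt(runif(n)), argument = runif(n, 0, pi))
}
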