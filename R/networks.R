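#' Topology generators: ring, lattice, random row-normalized
#'
#' The three connectivity families of the study. `ring_unidirectional()`
#' couples node `k` to its predecessor `k - 1` (mod `N`) with weight
#' `W_E`; its scaled spectrum is the `N`-th roots of unity, so the
#' second-largest eigenvalue approaches the unit circle's right edge as
#' `N` grows. `ring_lattice()` couples each node symmetrically to its two
#' nearest neighbours with weight `W_E / 2`; its scaled spectrum is
#' `cos(2*pi*k/N)`, purely real. `random_row_normalized()` draws dense
#' off-diagonal weights i.i.d. uniform on (0, 1), zeroes the diagonal (no
#' self-coupling), and rescales each row to sum to `W_E`; its non-Perron
#' eigenvalues cluster near the origin as `N` grows.
#'
#' All generators return plain weight matrices; wrap them in
#' [network_spec()] together with a delay specification to simulate.
#'
#' @param N Number of nodes (`>= 1` for the unidirectional ring, `>= 3`
#'   for the lattice, `>= 2` for the random family).
#' @param W_E Global coupling: the row sum of every returned matrix.
#' @param seed Integer seed making the random family reproducible.
#' @return An `N x N` nonnegative weight matrix with rows summing to
#'   `W_E`.
#' @examples
#' spectrum(ring_unidirectional(4, 2), W_E = 2)  # scaled: 4th roots of unity
#' @export
ring_unidirectional <- function(N, W_E = 1) {
  if (N < 1) stop("`N` must be at least 1", call. = FALSE)
  W <- matrix(0, N, N)
  W[cbind(1:N, c(N, seq_len(N - 1)))] <- W_E
  W
}

#' @rdname ring_unidirectional
#' @export
ring_lattice <- function(N, W_E = 1) {
  if (N < 3) stop("`N` must be at least 3 for a ring lattice", call. = FALSE)
  W <- matrix(0, N, N)
  W[cbind(1:N, c(N, seq_len(N - 1)))] <- W_E / 2
  W[cbind(1:N, c(seq_len(N - 1) + 1, 1))] <- W_E / 2
  W
}

#' @rdname ring_unidirectional
#' @export
random_row_normalized <- function(N, W_E = 1, seed = 1) {
  if (N < 2) stop("`N` must be at least 2", call. = FALSE)
  W <- with_seed(seed, matrix(runif(N * N), N, N))
  diag(W) <- 0
  W * (W_E / rowSums(W))
}

# Evaluate code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Sample heterogeneous conduction delays on a network's edges
#'
#' Each existing edge (`W > 0`) receives a delay drawn from a Beta
#' distribution rescaled to the support `(0, 2 * mean_eps)`, and the whole
#' sample is then multiplied by one constant so that its mean over edges
#' equals `mean_eps` exactly. Entries without an edge keep delay 0 (they
#' carry no signal). The symmetric default shape `alpha = beta = 2` puts
#' the distribution's mass around the target mean while keeping all draws
#' strictly positive; large equal shapes approach the homogeneous limit.
#'
#' @param W Nonnegative weight matrix whose positive entries define the
#'   edges to receive delays.
#' @param mean_eps Target sample mean of the delays over edges, `> 0`.
#' @param alpha,beta Beta shape parameters, `> 0`.
#' @param seed Integer seed; a fixed seed reproduces the sample exactly.
#' @return An object of class `wc_delay_sample`: list with the delay
#'   matrix `eps`, `target_mean`, `seed`, `alpha`, `beta`.
#' @examples
#' W <- ring_unidirectional(6, 2.115)
#' d <- heterogeneous_delays(W, mean_eps = 0.1, seed = 42)
#' mean(d$eps[W > 0]) # exactly 0.1
#' @export
heterogeneous_delays <- function(W, mean_eps = 0.1, alpha = 2, beta = 2,
                                 seed = 1) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (mean_eps <= 0) stop("`mean_eps` must be positive", call. = FALSE)
  if (alpha <= 0 || beta <= 0) stop("Beta shapes must be positive", call. = FALSE)
  edges <- which(W > 0)
  if (!length(edges)) stop("`W` has no edges to delay", call. = FALSE)
  s <- seed
  repeat {
    draws <- with_seed(s, rbeta(length(edges), alpha, beta)) * 2 * mean_eps
    if (mean(draws) > 0 && all(draws > 0)) break
    message("degenerate delay sample; resampling with seed ", s + 1)
    s <- s + 1
  }
  draws <- draws * (mean_eps / mean(draws))
  eps <- matrix(0, nrow(W), ncol(W))
  eps[edges] <- draws
  structure(list(eps = eps, target_mean = mean_eps, seed = s,
                 alpha = alpha, beta = beta),
            class = "wc_delay_sample")
}

#' @export
print.wc_delay_sample <- function(x, ...) {
  cat(sprintf(
    "<wc_delay_sample> %d delayed edges, mean = %g, Beta(%g, %g), seed %d\n",
    sum(x$eps > 0), x$target_mean, x$alpha, x$beta, x$seed))
  invisible(x)
}

#' Eigenvalue spectrum of a connectivity matrix, raw and scaled
#'
#' Scaled eigenvalues are the raw eigenvalues divided by the global
#' coupling `W_E`, which places the spectrum of any nonnegative
#' row-normalized matrix on or inside the unit disk with the Perron
#' eigenvalue at exactly 1 (eigenvector all-ones: the synchronous
#' direction). The Master Stability Function is evaluated at these scaled
#' coordinates.
#'
#' @param W Square connectivity matrix.
#' @param W_E Global coupling used for scaling; defaults to the common
#'   row sum of `W` when rows are (numerically) constant.
#' @return A tibble of class `wc_spectrum`, ordered by descending real
#'   part (ties by descending modulus), with columns `re`, `im` (raw),
#'   `re_scaled`, `im_scaled`, `mod_scaled`, and `is_perron` marking the
#'   eigenvalue with scaled value 1.
#' @export
spectrum <- function(W, W_E = NULL) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("`W` must be a square matrix", call. = FALSE)
  if (is.null(W_E)) {
    rs <- rowSums(W)
    if (diff(range(rs)) > 1e-8 * max(abs(rs), 1))
      stop("rows are not normalized; supply `W_E` explicitly", call. = FALSE)
    W_E <- rs[1]
  }
  ev <- eigen(W, only.values = TRUE)$values
  ev <- as.complex(ev)
  ord <- order(-Re(ev), -Mod(ev))
  ev <- ev[ord]
  sc <- ev / W_E
  out <- tibble::tibble(
    re = Re(ev), im = Im(ev),
    re_scaled = Re(sc), im_scaled = Im(sc), mod_scaled = Mod(sc),
    is_perron = FALSE)
  ip <- which(abs(sc - 1) < 1e-8)
  if (length(ip)) out$is_perron[ip[1]] <- TRUE
  attr(out, "W_E") <- unname(W_E)
  class(out) <- c("wc_spectrum", class(out))
  out
}

#' Read and write connectivity matrices as delimited text
#'
#' Plain whitespace-delimited numbers, row-major, no header -- the format
#' used for externally produced (e.g. connectome-style) weight matrices.
#' The reader validates nonnegativity and records the row sums.
#'
#' @param W Matrix to write.
#' @param path File path.
#' @return `read_matrix()` returns the matrix with a `row_sums`
#'   attribute; `write_matrix()` returns `path` invisibly.
#' @export
write_matrix <- function(W, path) {
  stopifnot(is.matrix(W))
  utils::write.table(W, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  W <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(W) <- NULL
  if (nrow(W) != ncol(W)) stop("matrix in file is not square", call. = FALSE)
  if (any(!is.finite(W)) || any(W < 0))
    stop("matrix entries must be nonnegative and finite", call. = FALSE)
  attr(W, "row_sums") <- rowSums(W)
  W
}

#' Export a spectrum as CSV
#'
#' @param sp A [spectrum()] result.
#' @param path Output path (columns `re`, `im`, `re_scaled`, `im_scaled`).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(sp, path) {
  stopifnot(inherits(sp, "wc_spectrum"))
  write.csv(sp[c("re", "im", "re_scaled", "im_scaled")], path,
            row.names = FALSE)
  invisible(path)
}
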