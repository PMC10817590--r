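#' @useDynLib oculotex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

utils::globalVariables(c("column", "feature", "state"))

# Canonical neuroretinal layer order (inner to outer).
NEURORETINA_LAYERS <- c("RNFL", "GCL", "IPL", "INL", "OPL", "ONL")

# En-face quadrants after left-eye flipping:
# Q1 temporal-superior, Q2 nasal-superior, Q3 temporal-inferior,
# Q4 nasal-inferior.
QUADRANTS <- c("Q1", "Q2", "Q3", "Q4")

EYES <- c("OD", "OS")

.oculotex_cache <- new.env(parent = emptyenv())

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_preserved_rng <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible RNG substream seed
#'
#' Hashes `(seed, participant_id, eye)` into a 31-bit integer so that each
#' scan draws from its own substream: adding participants to a cohort never
#' perturbs the volumes of existing ones.
#'
#' @param seed Base integer seed.
#' @param ... Character or numeric labels identifying the substream.
#' @return A single integer in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, ...) {
  key <- paste(c(format(as.integer(seed)), as.character(list(...))),
               collapse = "\r")
  as.integer(poly_hash(key))
}

# Truncated (6 sigma) 1-D Gaussian convolution matrix with renormalized rows,
# memoized on (n, sigma).
gauss_kernel_matrix <- function(n, sigma) {
  key <- sprintf("K_%d_%g", n, sigma)
  K <- .oculotex_cache[[key]]
  if (!is.null(K)) return(K)
  idx <- seq_len(n)
  D <- outer(idx, idx, `-`)
  K <- exp(-(D * D) / (2 * sigma * sigma))
  K[abs(D) > 6 * sigma] <- 0
  K <- K / rowSums(K)
  .oculotex_cache[[key]] <- K
  K
}

gauss_kernel_matrix_t <- function(n, sigma) {
  key <- sprintf("Kt_%d_%g", n, sigma)
  K <- .oculotex_cache[[key]]
  if (is.null(K)) {
    K <- t(gauss_kernel_matrix(n, sigma))
    .oculotex_cache[[key]] <- K
  }
  K
}

# Stationary smoothed-white-noise field on an n_r x n_c grid. `sigma` is the
# correlation length in isotropic (B-scan pixel) units; the column axis is
# `aspect` times finer, so the column kernel is scaled accordingly. The
# realized field is rescaled to sample standard deviation `sd`. Consumes RNG.
smooth_noise_field <- function(n_r, n_c, sigma, sd, aspect = 1) {
  if (sd == 0) return(matrix(0, n_r, n_c))
  W <- matrix(stats::rnorm(n_r * n_c), n_r, n_c)
  if (sigma > 0) {
    Kr <- gauss_kernel_matrix(n_r, sigma)
    Kct <- gauss_kernel_matrix_t(n_c, sigma * aspect)
    W <- Kr %*% W %*% Kct
  }
  # standardize the realization: zero mean, exactly the target sd
  W <- W - mean(W)
  s <- stats::sd(W)
  if (s == 0) return(matrix(0, n_r, n_c))
  W * (sd / s)
}

# Coarse-grid variant for slowly varying surfaces (interface undulations):
# the field is generated on the isotropic n_r x n_r grid and expanded to
# n_r x n_c by linear interpolation along columns. Valid when `sigma` is
# much larger than the column spacing, which holds for interface smoothness
# scales; texture fields use the full-resolution generator above.
smooth_noise_field_coarse <- function(n_r, n_c, sigma, sd, aspect = 1) {
  if (sd == 0) return(matrix(0, n_r, n_c))
  if (n_c == n_r) return(smooth_noise_field(n_r, n_c, sigma, sd, 1))
  W <- smooth_noise_field(n_r, n_r, sigma, sd, 1)
  # column c (fine grid) sits at coarse position (c - 0.5) / aspect + 0.5
  x <- (seq_len(n_c) - 0.5) / aspect + 0.5
  i0 <- pmax(1L, pmin(n_r - 1L, floor(x)))
  w1 <- pmin(1, pmax(0, x - i0))
  W[, i0, drop = FALSE] * rep(1 - w1, each = n_r) +
    W[, i0 + 1L, drop = FALSE] * rep(w1, each = n_r)
}

match_layer <- function(layer, layers) {
  if (!layer %in% layers) {
    stop(sprintf("unknown layer '%s'; available: %s", layer,
                 paste(layers, collapse = ", ")), call. = FALSE)
  }
  match(layer, layers)
}

# Deterministic 31-bit hash of an R object, for provenance stamping of
# configs and reports.
config_hash <- function(x) {
  txt <- paste(deparse(x, control = "all"), collapse = "\n")
  sprintf("%08x", poly_hash(txt))
}

# Polynomial rolling hash modulo the Mersenne prime 2^31 - 1, computed in
# exact double arithmetic (all intermediates stay below 2^53).
poly_hash <- function(txt) {
  bytes <- utf8ToInt(txt)
  m <- 2147483647
  h <- 17
  for (b in bytes) h <- (h * 1000003 + b) %% m
  h
}
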