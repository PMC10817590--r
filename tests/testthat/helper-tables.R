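# Build a feature table from explicit per-eye participant x feature matrices.
table_from_matrices <- function(M_od, M_os, sex = "female") {
  stopifnot(identical(dimnames(M_od), dimnames(M_os)))
  mk <- function(M, eye) {
    keys <- colnames(M)
    parts <- regmatches(keys, regexec("^(.*) \\(([A-Z]+)/(Q[1-4])\\)$", keys))
    data.frame(
      participant_id = rep(rownames(M), times = ncol(M)),
      sex = sex, age = 40, eye = eye,
      layer = rep(vapply(parts, `[`, "", 3), each = nrow(M)),
      quadrant = rep(vapply(parts, `[`, "", 4), each = nrow(M)),
      feature = rep(vapply(parts, `[`, "", 2), each = nrow(M)),
      value = as.vector(M), stringsAsFactors = FALSE
    )
  }
  rbind(mk(M_od, "OD"), mk(M_os, "OS"))
}

named_matrix <- function(data, keys, n) {
  matrix(data, n, length(keys), dimnames = list(sprintf("P%02d", seq_len(n)), keys))
}

# A small synthetic feature table with known structure: latent factors give
# correlated cliques; one feature carries a true interocular shift.
analysis_fixture <- function(n = 30, shift = 0, seed = 1) {
  set.seed(seed)
  keys <- c(sprintf("%s (IPL/Q4)", c("Entropy", "Energy", "Sum Entropy")),
            sprintf("%s (GCL/Q%d)", rep(c("Contrast", "SSV"), each = 4), 1:4))
  k <- length(keys)
  f <- rnorm(n)
  mk <- function(extra = 0) {
    M <- sapply(seq_len(k), function(j) {
      if (j <= 3) (if (j == 2) -1 else 1) * f + rnorm(n, sd = 0.3)
      else rnorm(n)
    })
    # the interocular shift moves the whole collinear clique, so whichever
    # representative survives decorrelation carries it
    M[, 1:3] <- M[, 1:3] + extra
    dimnames(M) <- list(sprintf("P%02d", seq_len(n)), keys)
    M
  }
  table_from_matrices(mk(), mk(extra = shift))
}
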