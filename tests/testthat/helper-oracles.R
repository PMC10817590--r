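# Independent brute-force oracles, written directly from the definitions and
# deliberately naive: explicit loops, no sharing with the package internals.

# Enumerate every ordered pixel pair at displacement (dr, dc), pooling the
# opposite direction, and tabulate level co-occurrences.
naive_glcm <- function(tile, dr, dc, n_levels) {
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(tile); nc <- ncol(tile)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      r2 <- r + dr; c2 <- c + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      i <- tile[r, c]; j <- tile[r2, c2]
      if (is.na(i) || is.na(j)) next
      counts[i + 1, j + 1] <- counts[i + 1, j + 1] + 1
      counts[j + 1, i + 1] <- counts[j + 1, i + 1] + 1
    }
  }
  if (sum(counts) == 0) return(NULL)
  counts / sum(counts)
}

naive_angle_offset <- function(angle, d = 1) {
  list(`0` = c(0, d), `45` = c(-d, d), `90` = c(-d, 0),
       `135` = c(-d, -d))[[as.character(angle)]]
}

# All 21 features from first principles with double loops over i, j = 1..N.
naive_features <- function(P) {
  n <- nrow(P)
  lg2 <- function(x) log(x, base = 2)
  px <- numeric(n); py <- numeric(n)
  for (i in 1:n) for (j in 1:n) {
    px[i] <- px[i] + P[i, j]
    py[j] <- py[j] + P[i, j]
  }
  mu_x <- sum((1:n) * px); mu_y <- sum((1:n) * py)
  sd_x <- sqrt(sum(((1:n) - mu_x)^2 * px))
  sd_y <- sqrt(sum(((1:n) - mu_y)^2 * py))
  p_sum <- numeric(2 * n - 1)   # index k-1 holds k = 2..2n
  p_dif <- numeric(n)           # index k+1 holds k = 0..n-1
  for (i in 1:n) for (j in 1:n) {
    p_sum[i + j - 1] <- p_sum[i + j - 1] + P[i, j]
    p_dif[abs(i - j) + 1] <- p_dif[abs(i - j) + 1] + P[i, j]
  }
  ent <- function(p) -sum(vapply(p, function(v) if (v > 0) v * lg2(v) else 0, 0))

  f <- c()
  f["Autocorrelation"] <- sum(outer(1:n, 1:n) * P)
  f["Cluster Prominence"] <- sum(outer(1:n, 1:n, function(i, j) (i + j - mu_x - mu_y)^4) * P)
  f["Cluster Shade"] <- sum(outer(1:n, 1:n, function(i, j) (i + j - mu_x - mu_y)^3) * P)
  f["Contrast"] <- sum(outer(1:n, 1:n, function(i, j) (i - j)^2) * P)
  f["Correlation"] <- if (sd_x > 0 && sd_y > 0) {
    (sum(outer(1:n, 1:n) * P) - mu_x * mu_y) / (sd_x * sd_y)
  } else 0
  f["Difference Entropy"] <- ent(p_dif)
  mu_d <- sum((0:(n - 1)) * p_dif)
  f["Difference Variance"] <- sum(((0:(n - 1)) - mu_d)^2 * p_dif)
  f["Dissimilarity"] <- sum(outer(1:n, 1:n, function(i, j) abs(i - j)) * P)
  f["Energy"] <- sum(P^2)
  f["Entropy"] <- ent(as.vector(P))
  f["Homogeneity"] <- sum(P / outer(1:n, 1:n, function(i, j) 1 + (i - j)^2))
  hx <- ent(px); hy <- ent(py)
  hxy1 <- 0; hxy2 <- 0
  for (i in 1:n) for (j in 1:n) {
    q <- px[i] * py[j]
    if (q > 0) {
      hxy1 <- hxy1 - P[i, j] * lg2(q)
      hxy2 <- hxy2 - q * lg2(q)
    }
  }
  f["IMC1"] <- if (max(hx, hy) > 0) (f[["Entropy"]] - hxy1) / max(hx, hy) else 0
  f["IMC2"] <- sqrt(max(0, 1 - exp(-2 * (hxy2 - f[["Entropy"]]))))
  f["Inverse Difference"] <- sum(P / outer(1:n, 1:n, function(i, j) 1 + abs(i - j)))
  f["IDMN"] <- sum(P / outer(1:n, 1:n, function(i, j) 1 + (i - j)^2 / n^2))
  f["IDN"] <- sum(P / outer(1:n, 1:n, function(i, j) 1 + abs(i - j) / n))
  f["Maximum Probability"] <- max(P)
  f["Sum Average"] <- sum((2:(2 * n)) * p_sum)
  f["Sum Entropy"] <- ent(p_sum)
  f["SSV"] <- sum(outer(1:n, 1:n, function(i, j) (i - mu_x)^2) * P)
  f["Sum Variance"] <- sum(((2:(2 * n)) - f[["Sum Average"]])^2 * p_sum)
  f[glcm_feature_names()]
}

# Random quantized tile, optionally with invalid pixels.
random_tile <- function(nr, nc, n_levels, na_frac = 0) {
  tile <- matrix(sample.int(n_levels, nr * nc, replace = TRUE) - 1L, nr, nc)
  if (na_frac > 0) {
    drop <- sample.int(nr * nc, ceiling(na_frac * nr * nc))
    tile[drop] <- NA_integer_
  }
  tile
}

# Random normalized symmetric GLCM.
random_glcm <- function(n_levels, sparse = FALSE) {
  A <- matrix(stats::rexp(n_levels^2), n_levels, n_levels)
  if (sparse) A[sample.int(n_levels^2, floor(n_levels^2 * 0.7))] <- 0
  P <- A + t(A)
  if (sum(P) == 0) P[1, 1] <- 1
  P / sum(P)
}
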