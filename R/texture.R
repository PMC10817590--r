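#' The 21 GLCM texture features, in canonical order
#'
#' @return Character vector of feature names.
#' @export
glcm_feature_names <- function() {
  c("Autocorrelation", "Cluster Prominence", "Cluster Shade", "Contrast",
    "Correlation", "Difference Entropy", "Difference Variance",
    "Dissimilarity", "Energy", "Entropy", "Homogeneity", "IMC1", "IMC2",
    "Inverse Difference", "IDMN", "IDN", "Maximum Probability",
    "Sum Average", "Sum Entropy", "SSV", "Sum Variance")
}

# GLCM orientation angles (degrees) and their (row, col) displacements for
# distance 1; rows grow downward (superior -> inferior), columns rightward
# (temporal -> nasal). Opposite directions are pooled, so signs are a
# convention only.
GLCM_ANGLES <- c(0, 45, 90, 135)
glcm_offset <- function(angle, d = 1L) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' GLCM configuration
#'
#' @param distance Pixel-pair distance `d` (>= 1).
#' @param n_levels Number of grey levels after quantization (>= 2).
#' @param sum_variance_about Centre of the Sum Variance moment: the Sum
#'   Average (the standard correction of a known misprint in the original
#'   feature list) or the Sum Entropy (the misprinted form).
#' @param diff_variance `"variance"`: Difference Variance is the variance of
#'   the grey-level-difference distribution `p_(x-y)`; `"mean_square"`: its
#'   raw second moment.
#' @param quantization `"fixed"` (default): bin the full 0-255 reflectivity
#'   range; `"per_image"`: min-max binning over the valid pixels of each
#'   image. Per-image scaling removes acquisition brightness/gain offsets
#'   between eyes, but its image-global scale couples all quadrants of a
#'   layer (the realized min-max is shared), which masks quadrant-localized
#'   asymmetries; on brightness-homogeneous data fixed-range binning
#'   preserves quadrant resolution.
#' @return An object of class `glcm_config`.
#' @export
glcm_config <- function(distance = 1L, n_levels = 16L,
                        sum_variance_about = c("sum_average", "sum_entropy"),
                        diff_variance = c("variance", "mean_square"),
                        quantization = c("fixed", "per_image")) {
  if (distance < 1) stop("`distance` must be >= 1", call. = FALSE)
  if (n_levels < 2) stop("`n_levels` must be >= 2", call. = FALSE)
  structure(list(distance = as.integer(distance),
                 n_levels = as.integer(n_levels),
                 sum_variance_about = match.arg(sum_variance_about),
                 diff_variance = match.arg(diff_variance),
                 quantization = match.arg(quantization)),
            class = "glcm_config")
}

#' Down-sample an MVF image to an isotropic square grid
#'
#' The native en-face grid has `n_ascan / n_bscan` times more columns than
#' rows over the same physical extent; mean-pooling each run of
#' `n_ascan / n_bscan` consecutive columns (4:1 for the 128 x 512 default)
#' yields isotropic sampling. A pooled pixel is invalid only when all its
#' source pixels are invalid; otherwise it is the mean of the valid ones.
#'
#' @param mvf An `mvf_image` whose column count is an integer multiple of
#'   its row count.
#' @return The pooled square `mvf_image`.
#' @export
downsample_mvf <- function(mvf) {
  stopifnot(inherits(mvf, "mvf_image"))
  nr <- nrow(mvf$values); nc <- ncol(mvf$values)
  if (nc %% nr != 0) {
    stop("column count must be an integer multiple of row count", call. = FALSE)
  }
  f <- nc %/% nr
  v <- mvf$values
  v[!mvf$mask] <- NA_real_
  out <- pool_columns_cpp(v, f)
  npix <- nr * nr
  mvf$values <- matrix(out[seq_len(npix)], nr, nr)
  mvf$mask <- matrix(out[npix + seq_len(npix)] > 0, nr, nr)
  mvf
}

#' Quantize an MVF image to discrete grey levels
#'
#' Linear equal-width binning into `n_levels` levels. With fixed
#' quantization (the default) the bins span the full 0-255 range; with
#' per-image quantization they span the min-max range of the valid pixels
#' of this image (see [glcm_config()] for the trade-off). The maximum maps
#' to level `n_levels - 1`; a constant image maps to level 0.
#'
#' @param mvf An `mvf_image` with at least one valid pixel.
#' @param config A [glcm_config()].
#' @return An object of class `quantized_image`: list with `levels`
#'   (integer matrix in `0..n_levels-1`, `NA` where invalid), `mask`,
#'   `n_levels`.
#' @export
quantize_mvf <- function(mvf, config = glcm_config()) {
  stopifnot(inherits(mvf, "mvf_image"))
  n <- config$n_levels
  v <- mvf$values
  if (!any(mvf$mask)) stop("cannot quantize an all-invalid image", call. = FALSE)
  if (config$quantization == "fixed") {
    lo <- 0; hi <- 255
  } else {
    lo <- min(v[mvf$mask]); hi <- max(v[mvf$mask])
  }
  if (hi <= lo) {
    lev <- matrix(0L, nrow(v), ncol(v))
  } else {
    lev <- floor((v - lo) / (hi - lo) * n)
    lev[which(lev >= n)] <- n - 1L
    lev[which(lev < 0)] <- 0L
    storage.mode(lev) <- "integer"
  }
  lev[!mvf$mask] <- NA_integer_
  structure(list(levels = lev, mask = mvf$mask, n_levels = n),
            class = "quantized_image")
}

#' Partition a square quantized image into the retained analysis blocks
#'
#' The 128 x 128 image is tiled by a 7 x 7 grid of non-overlapping 18 x 18
#' blocks anchored at the top-left corner (pixels beyond column/row 126 are
#' unused). The central (4th) row and column of the grid are discarded to
#' exclude the fovea, leaving 36 blocks in four 3 x 3 quadrant groups:
#' Q1 temporal-superior, Q2 nasal-superior, Q3 temporal-inferior,
#' Q4 nasal-inferior (on the orientation-standardised image).
#'
#' @param q A `quantized_image` (or anything with 128 x 128 `levels`).
#' @return An object of class `block_grid`: data frame with one row per
#'   retained block (`block`, `grid_row`, `grid_col`, `quadrant`, `row0`,
#'   `col0`) plus attributes `tile` (18) and `n_grid` (7).
#' @export
partition_blocks <- function(q) {
  lv <- if (inherits(q, "quantized_image")) q$levels else q
  if (nrow(lv) != 128 || ncol(lv) != 128) {
    stop("block partition expects a 128 x 128 image", call. = FALSE)
  }
  tile <- 18L; n_grid <- 7L; centre <- 4L
  idx <- expand.grid(grid_row = seq_len(n_grid), grid_col = seq_len(n_grid))
  idx <- idx[idx$grid_row != centre & idx$grid_col != centre, ]
  quadrant <- ifelse(idx$grid_row < centre,
                     ifelse(idx$grid_col < centre, "Q1", "Q2"),
                     ifelse(idx$grid_col < centre, "Q3", "Q4"))
  grid <- data.frame(
    block = sprintf("B%d%d", idx$grid_row, idx$grid_col),
    grid_row = idx$grid_row, grid_col = idx$grid_col,
    quadrant = quadrant,
    row0 = (idx$grid_row - 1L) * tile,
    col0 = (idx$grid_col - 1L) * tile,
    stringsAsFactors = FALSE
  )
  grid <- grid[order(grid$grid_row, grid$grid_col), ]
  rownames(grid) <- NULL
  attr(grid, "tile") <- tile
  attr(grid, "n_grid") <- n_grid
  class(grid) <- c("block_grid", "data.frame")
  grid
}

# Extract one block's level submatrix from a quantized image.
block_tile <- function(q, grid, i) {
  tile <- attr(grid, "tile")
  r <- grid$row0[i] + seq_len(tile)
  c <- grid$col0[i] + seq_len(tile)
  q$levels[r, c, drop = FALSE]
}

#' Compute a grey-level co-occurrence matrix
#'
#' Counts ordered pairs of levels at displacement `d` along `angle`,
#' pooling each direction with its opposite (180 degrees apart), which makes
#' the matrix symmetric; counts are then normalized to sum to one. Pairs
#' touching invalid (`NA`) pixels are skipped. A tile with no valid pair is
#' flagged degenerate.
#'
#' @param tile Integer matrix of quantized levels (`NA` = invalid), or a
#'   `quantized_image`.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param config A [glcm_config()].
#' @return An object of class `glcm`: list with `P` (normalized symmetric
#'   matrix `n_levels x n_levels`), `n_pairs` (valid ordered pair count
#'   before mirroring), `angle`, `degenerate`.
#' @export
compute_glcm <- function(tile, angle, config = glcm_config()) {
  if (inherits(tile, "quantized_image")) tile <- tile$levels
  n <- config$n_levels
  if (any(tile >= n, na.rm = TRUE) || any(tile < 0, na.rm = TRUE)) {
    stop("tile levels must lie in [0, n_levels - 1]", call. = FALSE)
  }
  off <- glcm_offset(angle, config$distance)
  counts <- glcm_counts_cpp(tile, off[1], off[2], n)
  tot <- sum(counts)
  if (tot == 0) {
    return(structure(list(P = counts, n_pairs = 0L, angle = angle,
                          degenerate = TRUE), class = "glcm"))
  }
  structure(list(P = counts / tot, n_pairs = as.integer(tot / 2), angle = angle,
                 degenerate = FALSE), class = "glcm")
}

#' Compute the 21 GLCM texture features
#'
#' Evaluates the feature set from a normalized symmetric GLCM and its
#' marginals (`p_x`, `p_y`, `p_(x+y)`, `p_(x-y)`), with grey levels indexed
#' `1..n_levels`. Logarithms are base 2 with the convention
#' `0 * log(0) = 0`. Correlation, IMC1 and IMC2 are defined as 0 when a
#' marginal standard deviation or entropy in their denominator vanishes
#' (constant tile). Sum Variance is, by default, the second moment of
#' `p_(x+y)` about the Sum Average; Difference Variance is the variance of
#' `p_(x-y)` (see [glcm_config()] for the selectable variants).
#'
#' @param glcm A `glcm` object (or a normalized co-occurrence matrix).
#' @param config A [glcm_config()].
#' @return Named numeric vector of the 21 features (see
#'   [glcm_feature_names()]).
#' @export
glcm_features <- function(glcm, config = glcm_config()) {
  P <- if (inherits(glcm, "glcm")) glcm$P else glcm
  if (inherits(glcm, "glcm") && glcm$degenerate) {
    stop("cannot compute features of a degenerate (pairless) GLCM", call. = FALSE)
  }
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM must be normalized to sum 1", call. = FALSE)
  out <- glcm_features_cpp(P,
                           match(config$sum_variance_about,
                                 c("sum_average", "sum_entropy")) - 1L,
                           match(config$diff_variance,
                                 c("variance", "mean_square")) - 1L)
  names(out) <- glcm_feature_names()
  out
}

#' Per-feature maximum across the four GLCM orientations
#'
#' The block's single feature vector is the elementwise maximum of the four
#' orientation vectors. Degenerate orientations (no valid pixel pair) are
#' excluded from the maximum; if all four are degenerate the block has no
#' value.
#'
#' @param vectors List of up to 4 feature vectors (`NULL` for degenerate
#'   orientations).
#' @return Named feature vector, or `NULL` if every orientation was
#'   degenerate.
#' @export
orientation_max <- function(vectors) {
  vectors <- Filter(Negate(is.null), vectors)
  if (length(vectors) == 0) return(NULL)
  Reduce(pmax, vectors)
}

#' Average block features per retinal quadrant
#'
#' Each quadrant value is the mean of its 9 blocks' feature values,
#' skipping blocks without a value; a quadrant with no valid block is `NA`.
#'
#' @param block_values Matrix of blocks x features (rows aligned with
#'   `grid`), `NA` rows for invalid blocks.
#' @param grid A `block_grid` from [partition_blocks()].
#' @return Matrix 4 x 21 (quadrants x features).
#' @export
aggregate_quadrants <- function(block_values, grid) {
  if (nrow(block_values) != nrow(grid)) {
    stop("block values and grid have different block counts", call. = FALSE)
  }
  out <- matrix(NA_real_, length(QUADRANTS), ncol(block_values),
                dimnames = list(QUADRANTS, colnames(block_values)))
  for (q in QUADRANTS) {
    rows <- block_values[grid$quadrant == q, , drop = FALSE]
    ok <- !is.na(rows[, 1])
    if (any(ok)) out[q, ] <- colMeans(rows[ok, , drop = FALSE])
  }
  out
}

#' Texture features of one orientation-standardised MVF image
#'
#' Runs the full texture chain: isotropic down-sampling, grey-level
#' quantization, 7 x 7 block partition with foveal exclusion, four GLCMs per
#' block, 21 features per GLCM, orientation maximum per block, and quadrant
#' averaging.
#'
#' @param mvf An `mvf_image` (orientation-standardised; 128 x 512 native
#'   grid by default).
#' @param config A [glcm_config()].
#' @return Data frame with columns `layer`, `quadrant`, `feature`, `value`
#'   (84 rows per layer image).
#' @export
mvf_texture_features <- function(mvf, config = glcm_config()) {
  small <- downsample_mvf(mvf)
  q <- quantize_mvf(small, config)
  grid <- partition_blocks(q)
  nfeat <- length(glcm_feature_names())
  block_values <- matrix(NA_real_, nrow(grid), nfeat,
                         dimnames = list(grid$block, glcm_feature_names()))
  sv <- match(config$sum_variance_about, c("sum_average", "sum_entropy")) - 1L
  dv <- match(config$diff_variance, c("variance", "mean_square")) - 1L
  for (b in seq_len(nrow(grid))) {
    tile <- block_tile(q, grid, b)
    fm <- tile_features_cpp(tile, config$n_levels, config$distance, sv, dv)
    ok <- !is.na(fm[1, ])
    if (any(ok)) {
      block_values[b, ] <- apply(fm[, ok, drop = FALSE], 1, max)
    }
  }
  quad <- aggregate_quadrants(block_values, grid)
  data.frame(
    layer = mvf$layer,
    quadrant = rep(rownames(quad), times = ncol(quad)),
    feature = rep(colnames(quad), each = nrow(quad)),
    value = as.vector(quad),
    stringsAsFactors = FALSE
  )
}
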