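test_that("down-sampling pools runs of columns and is mean-preserving", {
  v <- matrix(5, 128, 512)
  out <- downsample_mvf(as_mvf(v))
  expect_equal(dim(out$values), c(128, 128))
  expect_true(all(out$values == 5))

  v2 <- matrix(0, 128, 512)
  v2[1, 1:4] <- c(1, 2, 3, 4)
  out2 <- downsample_mvf(as_mvf(v2))
  expect_equal(out2$values[1, 1], 2.5)
})

test_that("pooled pixels are invalid only when all sources are invalid", {
  v <- matrix(10, 128, 512)
  v[1, 1:3] <- NA   # 3 of 4 sources invalid -> mean of the valid one
  v[2, 5:8] <- NA   # all 4 invalid -> masked
  out <- downsample_mvf(as_mvf(v))
  expect_equal(out$values[1, 1], 10)
  expect_true(out$mask[1, 1])
  expect_false(out$mask[2, 2])
  expect_true(is.na(out$values[2, 2]))
})

test_that("down-sampling rejects incompatible shapes", {
  expect_error(downsample_mvf(as_mvf(matrix(0, 128, 500))), "multiple")
})

test_that("quantization maps the valid range onto 16 levels", {
  ramp <- matrix(seq(0, 255, length.out = 128 * 128), 128, 128)
  q <- quantize_mvf(as_mvf(ramp), glcm_config(quantization = "per_image"))
  expect_equal(sort(unique(as.vector(q$levels))), 0:15)
  expect_equal(q$levels[128, 128], 15L)
  expect_true(max(q$levels, na.rm = TRUE) <= 15)

  flat <- quantize_mvf(as_mvf(matrix(7, 8, 8)),
                       glcm_config(quantization = "per_image"))
  expect_true(all(flat$levels == 0L))
})

test_that("fixed-range quantization bins 0-255 regardless of image content", {
  v <- matrix(c(0, 64, 128, 255), 2, 2)
  q <- quantize_mvf(as_mvf(v), glcm_config(quantization = "fixed"))
  expect_equal(as.vector(q$levels), c(0L, 4L, 8L, 15L))
  all_na <- as_mvf(matrix(NA_real_, 4, 4))
  expect_error(quantize_mvf(all_na), "all-invalid")
})

test_that("the block grid retains 36 non-central tiles in four 3x3 quadrants", {
  q <- quantize_mvf(as_mvf(matrix(runif(128 * 128, 0, 255), 128, 128)))
  grid <- partition_blocks(q)
  expect_equal(nrow(grid), 36)
  expect_equal(attr(grid, "tile"), 18L)
  expect_equal(attr(grid, "n_grid"), 7L)
  expect_false(any(grid$grid_row == 4 | grid$grid_col == 4))
  expect_equal(unname(table(grid$quadrant)[c("Q1", "Q2", "Q3", "Q4")]),
               rep(9L, 4), ignore_attr = TRUE)
  expect_equal(grid$quadrant[grid$grid_row == 1 & grid$grid_col == 1], "Q1")
  expect_equal(grid$quadrant[grid$grid_row == 7 & grid$grid_col == 7], "Q4")
  expect_equal(grid$quadrant[grid$grid_row == 1 & grid$grid_col == 7], "Q2")
  expect_equal(grid$quadrant[grid$grid_row == 7 & grid$grid_col == 1], "Q3")
  # tiles are disjoint and cover pixels 1..126 in each direction
  expect_equal(max(grid$row0) + 18, 126)
  expect_error(partition_blocks(matrix(0L, 64, 64)), "128")
})

test_that("GLCM counts match the worked 2x2 example and basic invariants", {
  tile <- matrix(c(0L, 1L, 0L, 1L), 2, 2)  # rows (0,0) and (1,1)
  g <- compute_glcm(tile, 0)
  expected <- matrix(0, 16, 16)
  expected[1, 1] <- 0.5; expected[2, 2] <- 0.5
  expect_equal(g$P, expected)
  expect_equal(g$n_pairs, 2L)

  const <- compute_glcm(matrix(3L, 4, 4), 90)
  expect_equal(const$P[4, 4], 1)
  expect_equal(sum(const$P), 1)

  # a tile with no valid pair at the displacement is flagged degenerate
  lonely <- matrix(NA_integer_, 3, 3); lonely[2, 2] <- 1L
  expect_true(compute_glcm(lonely, 0)$degenerate)
  expect_error(compute_glcm(matrix(99L, 2, 2), 0), "levels")
})

test_that("GLCM builder equals brute-force pair enumeration on random tiles", {
  set.seed(402)
  for (rep in 1:40) {
    nr <- sample(2:10, 1); nc <- sample(2:10, 1)
    n_levels <- sample(c(4L, 8L, 16L), 1)
    tile <- random_tile(nr, nc, n_levels, na_frac = ifelse(rep %% 3 == 0, 0.2, 0))
    cfg <- glcm_config(n_levels = n_levels)
    for (angle in c(0, 45, 90, 135)) {
      off <- naive_angle_offset(angle)
      oracle <- naive_glcm(tile, off[1], off[2], n_levels)
      got <- compute_glcm(tile, angle, cfg)
      if (is.null(oracle)) {
        expect_true(got$degenerate)
      } else {
        expect_equal(got$P, oracle, tolerance = 1e-12)
        expect_equal(sum(got$P), 1, tolerance = 1e-12)
        expect_equal(got$P, t(got$P))
      }
    }
  }
})

test_that("single-entry GLCMs give the degenerate feature values", {
  f <- glcm_features(compute_glcm(matrix(5L, 6, 6), 0))
  expect_equal(f[["Energy"]], 1)
  expect_equal(f[["Entropy"]], 0)
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Dissimilarity"]], 0)
  expect_equal(f[["Homogeneity"]], 1)
  expect_equal(f[["Maximum Probability"]], 1)
  expect_equal(f[["Correlation"]], 0)   # zero marginal sd convention
  expect_equal(f[["IMC1"]], 0)
  expect_equal(f[["IMC2"]], 0)
})

test_that("the two-level diagonal GLCM evaluates in closed form", {
  P <- matrix(0, 16, 16); P[1, 1] <- 0.5; P[2, 2] <- 0.5
  f <- glcm_features(P)
  expect_equal(f[["Energy"]], 0.5)
  expect_equal(f[["Entropy"]], 1)      # base-2
  expect_equal(f[["Contrast"]], 0)
  expect_equal(f[["Autocorrelation"]], 0.5 * 1 + 0.5 * 4)
  expect_equal(f[["Correlation"]], 1)  # perfectly dependent levels
  expect_equal(f[["Sum Average"]], 3)  # (2 + 4) / 2
})

test_that("all 21 feature formulas match the naive oracle on random GLCMs", {
  set.seed(707)
  cfg <- glcm_config()
  for (rep in 1:100) {
    n <- sample(c(4L, 8L, 16L), 1)
    P <- random_glcm(n, sparse = rep %% 2 == 0)
    expect_equal(glcm_features(P, cfg), naive_features(P), tolerance = 1e-10)
  }
})

test_that("feature variants change only their own feature", {
  set.seed(11)
  P <- random_glcm(16)
  base <- glcm_features(P, glcm_config())
  alt_sv <- glcm_features(P, glcm_config(sum_variance_about = "sum_entropy"))
  expect_false(isTRUE(all.equal(base[["Sum Variance"]], alt_sv[["Sum Variance"]])))
  expect_equal(base[setdiff(names(base), "Sum Variance")],
               alt_sv[setdiff(names(alt_sv), "Sum Variance")])
  alt_dv <- glcm_features(P, glcm_config(diff_variance = "mean_square"))
  mu_d <- sum((0:15) * sapply(0:15, function(k) sum(P[abs(row(P) - col(P)) == k])))
  expect_equal(alt_dv[["Difference Variance"]] - base[["Difference Variance"]],
               mu_d^2, tolerance = 1e-10)
})

test_that("unnormalized matrices are rejected", {
  expect_error(glcm_features(matrix(1, 4, 4)), "normalized")
})

test_that("orientation max takes the per-feature elementwise maximum", {
  v1 <- c(Contrast = 0.1, Energy = 0.9)
  v2 <- c(Contrast = 0.4, Energy = 0.2)
  v3 <- c(Contrast = 0.2, Energy = 0.5)
  v4 <- c(Contrast = 0.3, Energy = 0.1)
  expect_equal(orientation_max(list(v1, v2, v3, v4)),
               c(Contrast = 0.4, Energy = 0.9))
  expect_equal(orientation_max(list(v1, v1, v1, v1)), v1)
  expect_equal(orientation_max(list(NULL, v2, NULL, v3)),
               c(Contrast = 0.4, Energy = 0.5))
  expect_null(orientation_max(list(NULL, NULL, NULL, NULL)))
})

test_that("orientation-max features are invariant under horizontal mirroring", {
  set.seed(905)
  cfg <- glcm_config()
  for (rep in 1:20) {
    tile <- random_tile(18, 18, 16, na_frac = ifelse(rep %% 4 == 0, 0.1, 0))
    mirrored <- tile[, ncol(tile):1]
    vecs <- function(tl) lapply(c(0, 45, 90, 135), function(a) {
      g <- compute_glcm(tl, a, cfg)
      if (g$degenerate) NULL else glcm_features(g, cfg)
    })
    expect_equal(orientation_max(vecs(tile)), orientation_max(vecs(mirrored)),
                 tolerance = 1e-12)
  }
})

test_that("quadrant aggregation averages the valid blocks of each quadrant", {
  q <- quantize_mvf(as_mvf(matrix(runif(128 * 128, 0, 255), 128, 128)))
  grid <- partition_blocks(q)
  vals <- matrix(rep(seq_len(36), 2), 36, 2,
                 dimnames = list(grid$block, c("A", "B")))
  out <- aggregate_quadrants(vals, grid)
  for (qd in c("Q1", "Q2", "Q3", "Q4")) {
    expect_equal(out[qd, "A"], mean(vals[grid$quadrant == qd, "A"]))
  }
  # invalid blocks are skipped; all-invalid quadrants are NA
  vals[grid$quadrant == "Q1", ] <- NA
  vals[which(grid$quadrant == "Q2")[1:4], ] <- NA
  out2 <- aggregate_quadrants(vals, grid)
  expect_true(is.na(out2["Q1", "A"]))
  expect_equal(out2["Q2", "B"],
               mean(vals[grid$quadrant == "Q2", "B"], na.rm = TRUE))
  expect_error(aggregate_quadrants(vals[1:10, ], grid), "block counts")
})

test_that("the per-layer texture table has 84 rows within block-range bounds", {
  set.seed(31)
  mvf <- as_mvf(matrix(runif(128 * 512, 40, 220), 128, 512))
  tab <- mvf_texture_features(mvf)
  expect_equal(nrow(tab), 21 * 4)
  expect_equal(sort(unique(tab$quadrant)), c("Q1", "Q2", "Q3", "Q4"))
  expect_setequal(unique(tab$feature), glcm_feature_names())
  expect_true(all(tab$value[tab$feature == "Energy"] > 0))
  expect_true(all(tab$value[tab$feature == "Energy"] <= 1))
  expect_true(all(tab$value[tab$feature == "Entropy"] >= 0))
  expect_true(all(tab$value[tab$feature == "Contrast"] >= 0))
})

test_that("texture sd moves entropy up and energy down on synthetic layers", {
  p <- list(participant_id = "P1", sex = "female", age = 30)
  f <- function(sd, seed) {
    vc <- reduced_vconfig(texture_sd = sd)
    scan <- generate_eye_volume(p, "OD", vc, seed = seed)
    mvf <- standardise_orientation(compute_mvf(scan$volume, scan$interfaces, "IPL"))
    tab <- mvf_texture_features(mvf)
    c(entropy = mean(tab$value[tab$feature == "Entropy"]),
      energy = mean(tab$value[tab$feature == "Energy"]))
  }
  lo <- f(5, 77); hi <- f(15, 77)
  expect_gt(hi[["entropy"]], lo[["entropy"]])
  expect_lt(hi[["energy"]], lo[["energy"]])
})

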