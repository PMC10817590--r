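test_that("pairwise correlations implement the both-eyes rule", {
  set.seed(52)
  n <- 30
  x <- rnorm(n)
  keys <- c("Contrast (IPL/Q1)", "Contrast (IPL/Q2)", "Contrast (IPL/Q3)")
  # OD: col2 duplicates col1, col3 independent; OS: col2 = -col1 (|r|=1),
  # col3 correlated with col1 only in OS
  M_od <- named_matrix(c(x, x, rnorm(n)), keys, n)
  M_os <- named_matrix(c(x, -x, x + rnorm(n, sd = 0.1)), keys, n)
  rec <- pairwise_correlations(table_from_matrices(M_od, M_os), "female")

  r12 <- rec[rec$a == keys[1] & rec$b == keys[2], ]
  expect_equal(r12$r_od, 1)
  expect_equal(r12$r_os, -1)
  expect_true(r12$correlated)   # |r| >= 0.5 in both eyes, sign irrelevant

  r13 <- rec[rec$a == keys[1] & rec$b == keys[3], ]
  expect_gt(abs(r13$r_os), 0.5)
  expect_false(r13$correlated)  # only one eye exceeds the threshold
})

test_that("independent features are rarely flagged and constants never are", {
  set.seed(99)
  n <- 49
  keys <- sprintf("Contrast (IPL/Q%d)", 1:4)
  M_od <- named_matrix(c(rnorm(3 * n), rep(1, n)), keys, n)  # last is constant
  M_os <- named_matrix(c(rnorm(3 * n), rep(1, n)), keys, n)
  rec <- pairwise_correlations(table_from_matrices(M_od, M_os), "female")
  expect_false(any(rec$correlated))
  expect_true(all(is.na(rec$r_od[rec$a == keys[4] | rec$b == keys[4]])))
})

test_that("selection follows the worked three-feature trace", {
  # pairs: (A,B) r = 0.9/0.9, (A,C) r = 0.6/0.7, (B,C) r = 0.1/0.1
  # -> n: A = 2, B = 1, C = 1 -> keep {A}, discard {B, C}
  keys <- c("Contrast (IPL/Q1)", "Energy (IPL/Q1)", "Entropy (IPL/Q1)")
  rec <- data.frame(a = c(keys[1], keys[1], keys[2]),
                    b = c(keys[2], keys[3], keys[3]),
                    r_od = c(0.9, 0.6, 0.1), r_os = c(0.9, 0.7, 0.1),
                    correlated = c(TRUE, TRUE, FALSE),
                    stringsAsFactors = FALSE)
  attr(rec, "features") <- keys
  attr(rec, "threshold") <- 0.5
  class(rec) <- c("correlation_records", "data.frame")
  for (variant in c(FALSE, TRUE)) {
    sel <- select_uncorrelated(rec, recompute_after_discard = variant)
    expect_equal(sel$kept, keys[1])
    expect_setequal(sel$discarded$feature, keys[2:3])
    expect_equal(unique(sel$discarded$removed_by), keys[1])
  }
})

test_that("selection keeps everything when no pair is correlated in both eyes", {
  set.seed(5)
  n <- 40
  keys <- sprintf("Contrast (IPL/Q%d)", 1:4)
  M_od <- named_matrix(rnorm(4 * n), keys, n)
  M_os <- named_matrix(rnorm(4 * n), keys, n)
  rec <- pairwise_correlations(table_from_matrices(M_od, M_os), "female")
  sel <- select_uncorrelated(rec)
  expect_setequal(sel$kept, keys)
  expect_equal(nrow(sel$discarded), 0)
})

test_that("kept sets are always pairwise non-correlated (soundness property)", {
  set.seed(61)
  for (rep in 1:10) {
    n <- 25
    k <- 12
    keys <- sprintf("Contrast (%s/Q%d)", rep(c("IPL", "GCL", "INL"), each = 4), 1:4)
    # latent factors induce realistic correlated blocks
    f1 <- rnorm(n); f2 <- rnorm(n)
    mk <- function() named_matrix(sapply(1:k, function(j) {
      w <- (j %% 3) / 2
      w * f1 + (1 - w) * rnorm(n) + ifelse(j > 6, 0.8 * f2, 0)
    }), keys, n)
    M_od <- mk(); M_os <- mk()
    rec <- pairwise_correlations(table_from_matrices(M_od, M_os), "female")
    for (variant in c(FALSE, TRUE)) {
      sel <- select_uncorrelated(rec, recompute_after_discard = variant)
      expect_setequal(c(sel$kept, sel$discarded$feature), keys)
      bad <- rec$correlated & rec$a %in% sel$kept & rec$b %in% sel$kept
      expect_equal(sum(bad), 0)
    }
  }
})

test_that("the normality gate follows Shapiro-Wilk at the 10% level", {
  set.seed(314)
  normal <- rnorm(49)
  skewed <- rexp(49)
  g <- normality_gate(normal, skewed)
  expect_true(g$normal_od)
  expect_false(g$normal_os)
  expect_equal(g$p_od, shapiro.test(normal)$p.value)
  expect_error(normality_gate(rnorm(2), rnorm(2)), "at least 3")
  # borderline sample: gate is stricter than the usual 5% convention
  set.seed(4)
  x <- c(rnorm(45), 3.2, 3.4, -3.1, 2.9)
  p <- shapiro.test(x)$p.value
  if (p >= 0.05 && p < 0.10) {
    expect_false(normality_gate(x, rnorm(49))$normal_od)
  }
})

test_that("paired tests dispatch on the gate and match the reference stats", {
  set.seed(88)
  od <- rnorm(49, mean = 1)
  os <- rnorm(49)
  tt <- paired_test(od, os, TRUE, TRUE)
  expect_equal(tt$test, "paired-t")
  ref <- t.test(od - os)
  expect_equal(tt$p, ref$p.value, tolerance = 1e-12)
  expect_equal(tt$statistic, unname(ref$statistic), tolerance = 1e-12)
  # manual oracle for the t statistic
  d <- od - os
  expect_equal(tt$statistic, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-10)
  expect_lt(tt$p, 0.05)

  wt <- paired_test(od, os, TRUE, FALSE)
  expect_equal(wt$test, "wilcoxon")
  expect_equal(wt$p,
               wilcox.test(od, os, paired = TRUE, exact = FALSE,
                           correct = TRUE)$p.value)
  expect_lt(wt$p, 0.05)

  # swapping the eyes keeps p and negates the t statistic
  swapped <- paired_test(os, od, TRUE, TRUE)
  expect_equal(swapped$p, tt$p)
  expect_equal(swapped$statistic, -tt$statistic)

  identical_eyes <- paired_test(od, od, TRUE, TRUE)
  expect_true(identical_eyes$degenerate)
  expect_equal(identical_eyes$p, 1)
})

test_that("small non-parametric samples use the exact signed-rank distribution", {
  set.seed(12)
  od <- rnorm(12, 0.8); os <- rnorm(12)
  wt <- paired_test(od, os, FALSE, FALSE)
  expect_equal(wt$p, wilcox.test(od, os, paired = TRUE, exact = TRUE)$p.value)
})
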