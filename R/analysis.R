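#' Full interocular analysis of one sex group
#'
#' Runs the statistical chain on a feature table: pairwise Pearson
#' correlations per eye, decorrelation of the feature set, Shapiro-Wilk
#' normality gating, paired right-vs-left tests, and the three
#' multiple-comparison corrections (Bonferroni, Benjamini-Hochberg, Storey
#' q-values) over the family of kept features. Also emits a per-feature
#' state grid (correlated-out / non-significant / significant-uncorrected /
#' significant-corrected) and a count summary.
#'
#' @param features Feature table (see [extract_features_cohort()]).
#' @param group `"female"` or `"male"`.
#' @param alpha Significance level (default 0.05).
#' @param sw_level Normality-gate level (default 0.10).
#' @param r_threshold Correlation threshold (default 0.5).
#' @param lambda Storey tuning parameter (default 0.5).
#' @param recompute_after_discard Selection traversal variant (see
#'   [select_uncorrelated()]).
#' @return An object of class `group_analysis`: list with `group`,
#'   `correlations`, `selection`, `tests` (data frame), `corrections`
#'   (list of three `correction_result`s), `grid` (per-feature state data
#'   frame), `counts`.
#' @export
run_group_analysis <- function(features, group, alpha = 0.05, sw_level = 0.10,
                               r_threshold = 0.5, lambda = 0.5,
                               recompute_after_discard = FALSE) {
  group <- match.arg(group, c("female", "male"))
  M_od <- feature_matrix(features, group, "OD")
  M_os <- feature_matrix(features, group, "OS")
  if (!identical(rownames(M_od), rownames(M_os))) {
    stop("unpaired participants between OD and OS", call. = FALSE)
  }
  records <- pairwise_correlations(features, group, r_threshold)
  selection <- select_uncorrelated(records, recompute_after_discard)
  kept <- selection$kept

  tests <- do.call(rbind, lapply(kept, function(f) {
    od <- M_od[, f]; os <- M_os[, f]
    gate <- normality_gate(od, os, sw_level)
    ht <- paired_test(od, os, gate$normal_od, gate$normal_os)
    data.frame(feature = f, normal_od = gate$normal_od,
               normal_os = gate$normal_os, test = ht$test,
               statistic = ht$statistic, p = ht$p,
               degenerate = ht$degenerate, stringsAsFactors = FALSE)
  }))

  p <- stats::setNames(tests$p, tests$feature)
  corrections <- list(
    bonferroni = correct_bonferroni(p, alpha),
    benjamini_hochberg = correct_bh(p, alpha),
    storey = correct_storey(p, alpha, lambda)
  )

  all_feats <- attr(records, "features")
  state <- stats::setNames(rep("correlated-out", length(all_feats)), all_feats)
  state[kept] <- "non-significant"
  state[names(p)[p < alpha]] <- "significant-uncorrected"
  sig_methods <- lapply(corrections, function(cr) names(p)[cr$significant])
  corrected_sig <- unique(unlist(sig_methods))
  state[corrected_sig] <- "significant-corrected"
  methods_of <- vapply(all_feats, function(f) {
    paste(names(sig_methods)[vapply(sig_methods, function(s) f %in% s, logical(1))],
          collapse = "+")
  }, character(1))

  parts <- parse_feature_key(all_feats)
  grid <- data.frame(feature_id = all_feats, feature = parts$feature,
                     layer = parts$layer, quadrant = parts$quadrant,
                     state = unname(state[all_feats]),
                     corrected_by = unname(methods_of),
                     stringsAsFactors = FALSE)

  counts <- list(
    group = group,
    n_features = length(all_feats),
    n_kept = length(kept),
    n_nonparametric = sum(tests$test == "wilcoxon"),
    uncorrected = sum(p < alpha),
    bonferroni = sum(corrections$bonferroni$significant),
    benjamini_hochberg = sum(corrections$benjamini_hochberg$significant),
    storey = sum(corrections$storey$significant),
    pi0 = corrections$storey$pi0,
    fdr_estimate = corrections$storey$fdr_estimate
  )

  structure(list(group = group, correlations = records, selection = selection,
                 tests = tests, corrections = corrections, grid = grid,
                 counts = counts, alpha = alpha),
            class = "group_analysis")
}

parse_feature_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.*) \\(([A-Z]+)/(Q[1-4])\\)$", keys))
  list(feature = vapply(m, `[`, character(1), 2),
       layer = vapply(m, `[`, character(1), 3),
       quadrant = vapply(m, `[`, character(1), 4))
}

#' @export
print.group_analysis <- function(x, ...) {
  ct <- x$counts
  cat(sprintf("Interocular analysis, %s group\n", x$group))
  cat(sprintf("  features: %d total, %d kept after decorrelation\n",
              ct$n_features, ct$n_kept))
  cat(sprintf("  non-parametric tests: %d of %d\n", ct$n_nonparametric, ct$n_kept))
  cat(sprintf("  significant (p < %g): %d uncorrected; %d Bonferroni, %d BH, %d Storey\n",
              x$alpha, ct$uncorrected, ct$bonferroni, ct$benjamini_hochberg,
              ct$storey))
  cat(sprintf("  Storey: pi0 = %.3f, FDR(t = %g) = %.1f%%\n",
              ct$pi0, x$corrections$storey$t, 100 * ct$fdr_estimate))
  invisible(x)
}
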