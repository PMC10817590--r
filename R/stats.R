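feature_key <- function(feature, layer, quadrant) {
  sprintf("%s (%s/%s)", feature, layer, quadrant)
}

# Wide participant x feature matrix for one eye of one group. Row order is
# participant order; column order is the stable (feature, layer, quadrant)
# order of the table.
feature_matrix <- function(features, group, eye) {
  sub <- features[features$sex == group & features$eye == eye, , drop = FALSE]
  if (nrow(sub) == 0) stop("no rows for group '", group, "', eye ", eye,
                           call. = FALSE)
  key <- feature_key(sub$feature, sub$layer, sub$quadrant)
  keys <- unique(key)
  pids <- unique(sub$participant_id)
  M <- matrix(NA_real_, length(pids), length(keys),
              dimnames = list(pids, keys))
  M[cbind(match(sub$participant_id, pids), match(key, keys))] <- sub$value
  if (anyNA(M)) {
    bad <- colnames(M)[colSums(is.na(M)) > 0]
    stop("missing values for feature(s): ", paste(utils::head(bad, 5), collapse = "; "),
         call. = FALSE)
  }
  M
}

#' Pairwise feature correlations within a group
#'
#' Computes, for every unordered pair of features, the Pearson correlation
#' across the group's participants separately for right (OD) and left (OS)
#' eyes. A pair is flagged `correlated` when `|r| >= threshold` in *both*
#' eyes. Constant features have undefined correlations; these are treated
#' as not correlated.
#'
#' @param features Feature table (see [extract_features_cohort()]).
#' @param group `"female"` or `"male"`.
#' @param threshold Absolute correlation threshold (default 0.5).
#' @return An object of class `correlation_records`: data frame with
#'   columns `a`, `b`, `r_od`, `r_os`, `correlated`, plus attributes
#'   `features` (stable feature-id order) and `threshold`.
#' @export
pairwise_correlations <- function(features, group, threshold = 0.5) {
  group <- match.arg(group, c("female", "male"))
  M_od <- feature_matrix(features, group, "OD")
  M_os <- feature_matrix(features, group, "OS")
  if (!identical(dimnames(M_od), dimnames(M_os))) {
    stop("OD and OS feature tables are inconsistent", call. = FALSE)
  }
  if (nrow(M_od) < 3) stop("need at least 3 participants per group", call. = FALSE)
  r_od <- suppressWarnings(stats::cor(M_od))
  r_os <- suppressWarnings(stats::cor(M_os))
  keys <- colnames(M_od)
  ut <- upper.tri(r_od)
  idx <- which(ut, arr.ind = TRUE)
  rec <- data.frame(a = keys[idx[, 1]], b = keys[idx[, 2]],
                    r_od = r_od[ut], r_os = r_os[ut],
                    stringsAsFactors = FALSE)
  rec$correlated <- !is.na(rec$r_od) & !is.na(rec$r_os) &
    abs(rec$r_od) >= threshold & abs(rec$r_os) >= threshold
  attr(rec, "features") <- keys
  attr(rec, "threshold") <- threshold
  class(rec) <- c("correlation_records", "data.frame")
  rec
}

#' Decorrelate the feature set
#'
#' Features involved in no correlated pair are kept outright. The remaining
#' features are ranked by the decreasing number `n` of correlated partners,
#' ties broken by the decreasing sum of explained variance
#' `sum_i (r_OD,i^2 + r_OS,i^2)` over those partners, remaining ties by
#' stable feature order. The ranked list is traversed once: a feature not
#' yet discarded is kept and all its not-yet-kept correlated partners are
#' discarded. The kept set ends pairwise non-correlated
#' (`|r| < threshold` in at least one eye for every kept pair). With
#' `recompute_after_discard = TRUE`, ranks are recomputed on the surviving
#' graph after each keep (the alternative reading of the procedure); both
#' traversals yield a sound kept set.
#'
#' @param records A `correlation_records` object.
#' @param recompute_after_discard Recompute degrees after each keep.
#' @return An object of class `selection_result`: list with `kept`,
#'   `discarded` (data frame `feature`, `removed_by`), `n`, `ev_sum`.
#' @export
select_uncorrelated <- function(records, recompute_after_discard = FALSE) {
  stopifnot(inherits(records, "correlation_records"))
  feats <- attr(records, "features")
  cor_pairs <- records[records$correlated, , drop = FALSE]
  ev <- cor_pairs$r_od^2 + cor_pairs$r_os^2
  n <- stats::setNames(numeric(length(feats)), feats)
  ev_sum <- stats::setNames(numeric(length(feats)), feats)
  for (i in seq_len(nrow(cor_pairs))) {
    a <- cor_pairs$a[i]; b <- cor_pairs$b[i]
    n[a] <- n[a] + 1; n[b] <- n[b] + 1
    ev_sum[a] <- ev_sum[a] + ev[i]; ev_sum[b] <- ev_sum[b] + ev[i]
  }
  partners <- split(c(cor_pairs$b, cor_pairs$a), c(cor_pairs$a, cor_pairs$b))

  status <- stats::setNames(rep("free", length(feats)), feats)
  removed_by <- stats::setNames(rep(NA_character_, length(feats)), feats)
  status[n == 0] <- "kept"

  if (!recompute_after_discard) {
    contested <- feats[n > 0]
    ord <- contested[order(-n[contested], -ev_sum[contested],
                           match(contested, feats))]
    for (f in ord) {
      if (status[f] != "free") next
      status[f] <- "kept"
      for (p in partners[[f]]) {
        if (status[p] == "free") {
          status[p] <- "discarded"
          removed_by[p] <- f
        }
      }
    }
  } else {
    adj <- partners
    repeat {
      free <- names(status)[status == "free"]
      if (length(free) == 0) break
      deg <- vapply(free, function(f) sum(status[adj[[f]]] == "free"), numeric(1))
      evs <- vapply(free, function(f) {
        live <- adj[[f]][status[adj[[f]]] == "free"]
        idx <- (cor_pairs$a == f & cor_pairs$b %in% live) |
               (cor_pairs$b == f & cor_pairs$a %in% live)
        sum(ev[idx])
      }, numeric(1))
      if (all(deg == 0)) { status[free] <- "kept"; break }
      pick <- free[order(-deg, -evs, match(free, feats))][1]
      status[pick] <- "kept"
      for (p in adj[[pick]]) {
        if (status[p] == "free") {
          status[p] <- "discarded"
          removed_by[p] <- pick
        }
      }
    }
  }

  kept <- feats[status[feats] == "kept"]
  discarded <- feats[status[feats] == "discarded"]
  structure(
    list(kept = kept,
         discarded = data.frame(feature = discarded,
                                removed_by = unname(removed_by[discarded]),
                                stringsAsFactors = FALSE),
         n = n, ev_sum = ev_sum),
    class = "selection_result"
  )
}

#' Normality gate for the paired-test choice
#'
#' Shapiro-Wilk on each eye's sample at a conservative 10% level: a sample
#' is called normal when its Shapiro-Wilk p-value is at least `level`.
#'
#' @param od,os Per-eye samples (length >= 3).
#' @param level Significance level of the gate (default 0.10).
#' @return List with logicals `normal_od`, `normal_os` and the two
#'   Shapiro-Wilk p-values.
#' @export
normality_gate <- function(od, os, level = 0.10) {
  if (length(od) < 3 || length(os) < 3) {
    stop("normality gate needs at least 3 observations per eye", call. = FALSE)
  }
  sw <- function(x) {
    if (stats::sd(x) == 0) return(0)  # constant sample: clearly non-normal
    stats::shapiro.test(x)$p.value
  }
  p_od <- sw(od); p_os <- sw(os)
  list(normal_od = p_od >= level, normal_os = p_os >= level,
       p_od = p_od, p_os = p_os)
}

#' Paired right-vs-left test for one feature
#'
#' Paired-sample t-test when both eyes' samples pass the normality gate;
#' otherwise a Wilcoxon signed-rank test (zero differences dropped, tied
#' ranks averaged, exact distribution for up to 25 non-zero pairs, else a
#' continuity-corrected normal approximation). Two-sided p-values. If all
#' paired differences are zero the result is flagged degenerate with p = 1.
#'
#' @param od,os Paired per-eye samples (same participants, same order).
#' @param normal_od,normal_os Normality gate outcome (see
#'   [normality_gate()]).
#' @return List with `test` (`"paired-t"` or `"wilcoxon"`), `statistic`,
#'   `p`, `degenerate`.
#' @export
paired_test <- function(od, os, normal_od, normal_os) {
  if (length(od) != length(os)) stop("samples must be paired", call. = FALSE)
  d <- od - os
  use_t <- isTRUE(normal_od) && isTRUE(normal_os)
  test <- if (use_t) "paired-t" else "wilcoxon"
  if (all(d == 0)) {
    return(list(test = test, statistic = NA_real_, p = 1, degenerate = TRUE))
  }
  if (use_t) {
    ht <- stats::t.test(od, os, paired = TRUE)
    list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
         degenerate = FALSE)
  } else {
    nz <- sum(d != 0)
    ht <- suppressWarnings(
      stats::wilcox.test(od, os, paired = TRUE, exact = nz <= 25,
                         correct = TRUE)
    )
    list(test = test, statistic = unname(ht$statistic), p = ht$p.value,
         degenerate = FALSE)
  }
}
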