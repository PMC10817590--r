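new_correction_result <- function(method, p, alpha, significant, adjusted,
                                  extra = list()) {
  structure(c(list(method = method, m = length(p), alpha = alpha,
                   p = p, significant = significant, adjusted = adjusted),
              extra),
            class = "correction_result")
}

check_pvals <- function(p) {
  if (length(p) < 1) stop("need at least one p-value", call. = FALSE)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
}

#' Bonferroni correction
#'
#' Controls the family-wise error rate: a test is significant iff
#' `p < alpha / m`; adjusted p-values are `min(1, m * p)`.
#'
#' @param p Named or unnamed vector of p-values.
#' @param alpha Significance level (default 0.05).
#' @return A `correction_result` (method, `m`, `alpha`, `significant`
#'   logical vector, `adjusted`).
#' @export
correct_bonferroni <- function(p, alpha = 0.05) {
  check_pvals(p)
  m <- length(p)
  adjusted <- pmin(1, m * p)
  names(adjusted) <- names(p)
  new_correction_result("bonferroni", p, alpha,
                        significant = p < alpha / m,
                        adjusted = adjusted)
}

#' Benjamini-Hochberg step-up correction
#'
#' Finds the largest `k` such that the k-th smallest p-value satisfies
#' `p_(k) < k * alpha / m` and declares the `k` smallest p-values
#' significant; adjusted values are the standard monotone step-up transform
#' `min_(j >= i) (m * p_(j) / j)` capped at 1.
#'
#' @inheritParams correct_bonferroni
#' @return A `correction_result`.
#' @export
correct_bh <- function(p, alpha = 0.05) {
  check_pvals(p)
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k_ok <- which(ps < seq_len(m) * alpha / m)
  k <- if (length(k_ok)) max(k_ok) else 0L
  significant <- rep(FALSE, m)
  if (k > 0) significant[ord[seq_len(k)]] <- TRUE
  adjusted <- stats::p.adjust(p, method = "BH")
  names(significant) <- names(p)
  new_correction_result("benjamini_hochberg", p, alpha, significant, adjusted)
}

#' Storey q-value correction
#'
#' Estimates the proportion of true nulls as
#' `pi0 = #\{p > lambda\} / (m * (1 - lambda))` (capped at 1), the false
#' discovery rate at threshold `t` as
#' `FDR(t) = min(1, pi0 * m * t / max(#\{p <= t\}, 1))`, and q-values as
#' `q(p_(i)) = min_(j >= i) (pi0 * m * p_(j) / j)` capped at 1. A test is
#' significant when its q-value is below `alpha`. With `lambda = 0` the
#' estimate `pi0 = 1` and q-values coincide with Benjamini-Hochberg
#' adjusted p-values.
#'
#' @inheritParams correct_bonferroni
#' @param lambda Null-proportion tuning parameter in `[0, 1)` (default 0.5).
#' @param t Threshold at which the FDR point estimate is reported
#'   (default 0.05).
#' @return A `correction_result` with extra fields `pi0`, `fdr_estimate`,
#'   `lambda`, `t`; `adjusted` holds the q-values.
#' @export
correct_storey <- function(p, alpha = 0.05, lambda = 0.5, t = 0.05) {
  check_pvals(p)
  if (lambda < 0 || lambda >= 1) stop("`lambda` must lie in [0, 1)", call. = FALSE)
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / (m * (1 - lambda)))
  fdr <- min(1, pi0 * m * t / max(sum(p <= t), 1))
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- rev(cummin(rev(pmin(1, pi0 * m * ps / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  names(q) <- names(p)
  sig <- q < alpha
  new_correction_result("storey", p, alpha, significant = sig, adjusted = q,
                        extra = list(pi0 = pi0, fdr_estimate = fdr,
                                     lambda = lambda, t = t))
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("%s correction: m = %d, alpha = %g, significant = %d\n",
              x$method, x$m, x$alpha, sum(x$significant)))
  if (!is.null(x$pi0)) {
    cat(sprintf("  pi0 = %.3f, FDR(t = %g) = %.1f%%, lambda = %g\n",
                x$pi0, x$t, 100 * x$fdr_estimate, x$lambda))
  }
  invisible(x)
}
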