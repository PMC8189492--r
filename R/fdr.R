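#' Benjamini-Hochberg critical values
#'
#' For n tests ranked by ascending p-value, the rank-k critical value at a
#' target false discovery rate is `(k / n) * fdr_level`. The step-up rule
#' finds the highest-ranked p-value strictly below its critical value; that
#' test and every smaller p-value are declared significant.
#'
#' @inheritParams adjust_pvalues
#' @param fdr_level Target FDR in (0, 1).
#' @return A tibble in ascending rank order with columns `rank`, `id`, `p`,
#'   `critical_value`, and `significant` (the final step-up rejection flag,
#'   not merely the per-rank comparison).
#' @examples
#' df <- data.frame(p = c(0.0001, 0.01, 0.3))
#' bh_critical_values(df, fdr_level = 0.05)
#' @export
bh_critical_values <- function(data, p = p, id = NULL, fdr_level = 0.05) {
  stopifnot(fdr_level > 0, fdr_level < 1)
  pv <- if (inherits(data, "mt_pvalues")) data
        else validate_pvalues(data, p = {{ p }}, id = {{ id }})
  n <- nrow(pv)
  ord <- order(pv$p)
  k <- seq_len(n)
  crit <- (k / n) * fdr_level
  ps <- pv$p[ord]
  hits <- which(ps < crit)
  kstar <- if (length(hits)) max(hits) else 0L
  tibble(rank = k, id = pv$id[ord], p = ps,
         critical_value = crit, significant = k <= kstar)
}

# pi0 estimation on a bare numeric vector; clamped into [1/n, 1].
pi0_engine <- function(p, estimator) {
  n <- length(p)
  value <- switch(estimator,
    count_above_half = (2 / n) * sum(p > 0.5),
    twice_mean_p     = 2 * mean(p),
    abort(sprintf("unknown pi0 estimator '%s'", estimator),
          class = "mt_usage_error"))
  list(value = min(1, max(1 / n, value)), estimator = estimator, n_used = n)
}

#' Estimate the proportion of true null hypotheses
#'
#' Under the null, p-values are uniform on \[0, 1\]; alternatives concentrate
#' near zero. Both estimators exploit the upper half of that mixture:
#'
#' * `"count_above_half"`: `(2/n) * #\{p_i > 0.5\}` — twice the fraction of
#'   p-values in the half of the unit interval where alternatives are rare.
#' * `"twice_mean_p"`: `2 * mean(p)` — a uniform has mean 1/2, so twice the
#'   average of the observed p-values.
#'
#' Both are clamped into `[1/n, 1]`: pi0 is a proportion, and the floor
#' avoids a zero estimate (which would zero out every q-value).
#'
#' @inheritParams adjust_pvalues
#' @param estimator `"count_above_half"` (default) or `"twice_mean_p"`.
#' @return A one-row tibble with columns `pi0`, `estimator`, `n_used`.
#' @examples
#' estimate_pi0(data.frame(p = runif(100)))
#' @export
estimate_pi0 <- function(data, p = p,
                         estimator = c("count_above_half", "twice_mean_p")) {
  estimator <- match.arg(estimator)
  pv <- if (inherits(data, "mt_pvalues")) data
        else validate_pvalues(data, p = {{ p }})
  fit <- pi0_engine(pv$p, estimator)
  tibble(pi0 = fit$value, estimator = fit$estimator, n_used = fit$n_used)
}

#' Storey's positive false discovery rate at a rejection threshold
#'
#' Estimates the positive FDR incurred by calling every test with `p <= t`
#' significant: `min(1, pi0 * m * t / S(t))`, where m is the total number of
#' tests and `S(t)` the number of p-values at or below t. `pi0 * m * t` is
#' the expected number of true nulls landing below t; dividing by the
#' realised rejection count gives the estimated proportion of false
#' discoveries. The pFDR is defined conditionally on at least one rejection,
#' so `S(t) = 0` is an error.
#'
#' @inheritParams adjust_pvalues
#' @param threshold Rejection threshold t in (0, 1\].
#' @param pi0 Proportion of true nulls; estimated via `pi0_estimator` when
#'   `NULL`.
#' @param pi0_estimator See [estimate_pi0()].
#' @return A single number in \[0, 1\].
#' @examples
#' storey_fdr(data.frame(p = runif(100)), threshold = 0.05, pi0 = 1)
#' @export
storey_fdr <- function(data, p = p, threshold, pi0 = NULL,
                       pi0_estimator = c("count_above_half", "twice_mean_p")) {
  pi0_estimator <- match.arg(pi0_estimator)
  stopifnot(threshold > 0, threshold <= 1)
  pv <- if (inherits(data, "mt_pvalues")) data
        else validate_pvalues(data, p = {{ p }})
  if (is.null(pi0)) pi0 <- pi0_engine(pv$p, pi0_estimator)$value
  s_t <- sum(pv$p <= threshold)
  if (s_t == 0L) {
    abort(sprintf("no rejections at threshold %g: positive FDR is undefined",
                  threshold), class = "mt_data_error")
  }
  min(1, pi0 * nrow(pv) * threshold / s_t)
}

#' Proportion of false positives (PFP) at a rejection threshold
#'
#' The PFP is the ratio of expected false positives to expected rejections,
#' `E(V) / E(R)`, with numerator and denominator estimated separately:
#' `V_hat = pi0 * m * t` and `R_hat = S(t)`. Under these estimators —
#' the only ones constructible from the quantities the procedure defines —
#' the PFP coincides numerically with [storey_fdr()]; it is kept as its own
#' verb because the two error measures are conceptually distinct (the PFP
#' does not depend on the dependence structure or the number of tests).
#'
#' @inheritParams storey_fdr
#' @return A single number in \[0, 1\].
#' @export
pfp_estimate <- function(data, p = p, threshold, pi0 = NULL,
                         pi0_estimator = c("count_above_half", "twice_mean_p")) {
  storey_fdr(data, p = {{ p }}, threshold = threshold, pi0 = pi0,
             pi0_estimator = pi0_estimator)
}

#' Estimated FDR across a grid of rejection thresholds
#'
#' Evaluates [storey_fdr()] at each threshold, returning the rejection count
#' `S(t)` and the capped FDR estimate. Thresholds with no rejections get
#' `NA` (the positive FDR is undefined there) rather than an error, so the
#' full curve can be plotted.
#'
#' @inheritParams storey_fdr
#' @param thresholds Ascending thresholds in (0, 1\]; defaults to the
#'   observed p-values.
#' @return A tibble with columns `threshold`, `n_rejected`, `fdr`.
#' @export
fdr_curve <- function(data, p = p, thresholds = NULL, pi0 = NULL,
                      pi0_estimator = c("count_above_half", "twice_mean_p")) {
  pi0_estimator <- match.arg(pi0_estimator)
  pv <- if (inherits(data, "mt_pvalues")) data
        else validate_pvalues(data, p = {{ p }})
  if (is.null(pi0)) pi0 <- pi0_engine(pv$p, pi0_estimator)$value
  if (is.null(thresholds)) thresholds <- sort(unique(pv$p[pv$p > 0]))
  stopifnot(all(thresholds > 0), all(thresholds <= 1),
            !is.unsorted(thresholds))
  m <- nrow(pv)
  s_at <- vapply(thresholds, function(t) sum(pv$p <= t), integer(1))
  fdr_at <- ifelse(s_at > 0, pmin(1, pi0 * m * thresholds / pmax(s_at, 1L)), NA_real_)
  tibble(threshold = thresholds, n_rejected = s_at, fdr = fdr_at)
}

#' Expected number of false positives at a fixed threshold
#'
#' When all m null hypotheses are true, the expected count of p-values below
#' a threshold is `threshold * m` — e.g. screening 20,000 genes at p = 0.05
#' yields 1000 expected false positives. The same arithmetic applies to
#' q-value bookkeeping, where m is instead the number of tests called
#' significant and the threshold is the q-value.
#'
#' @param threshold Per-test rate in \[0, 1\].
#' @param m Number of tests the rate applies to.
#' @return `threshold * m`.
#' @examples
#' expected_false_positives(0.05, 20000)  # 1000
#' @export
expected_false_positives <- function(threshold, m) {
  stopifnot(threshold >= 0, threshold <= 1, m >= 1)
  threshold * m
}

#' Storey q-values
#'
#' Convenience wrapper for `adjust_pvalues(method = "qvalue")`: the q-value
#' of a test is the minimum estimated positive FDR over all rejection
#' thresholds at which that test would be called significant. See
#' [adjust_pvalues()] for details.
#'
#' @inheritParams adjust_pvalues
#' @return An `"mt_adjust"` tibble with a `q_value` column.
#' @export
qvalues <- function(data, p = p, id = NULL, fdr_level = 0.05, pi0 = NULL,
                    pi0_estimator = c("count_above_half", "twice_mean_p")) {
  adjust_pvalues(data, p = {{ p }}, id = {{ id }}, method = "qvalue",
                 fdr_level = fdr_level, pi0 = pi0,
                 pi0_estimator = match.arg(pi0_estimator))
}
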