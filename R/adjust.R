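#' Family-wise error rate for a family of comparisons
#'
#' Probability of at least one type I error across `c` independent
#' comparisons each run at per-comparison level `alpha_pc`:
#' `1 - (1 - alpha_pc)^c`. Monotone nondecreasing in both arguments.
#'
#' @param alpha_pc Per-comparison (per-contrast) error rate in \[0, 1\].
#' @param c Number of comparisons performed (positive integer).
#' @return The family-wise error rate, a number in \[0, 1\].
#' @examples
#' fwer(0.05, 20)
#' @export
fwer <- function(alpha_pc, c) {
  stopifnot(is.numeric(alpha_pc), alpha_pc >= 0, alpha_pc <= 1,
            is.numeric(c), c >= 1)
  1 - (1 - alpha_pc)^c
}

#' Bonferroni significance threshold
#'
#' The per-test cut-off `alpha / n`. A raw p-value is significant iff it is
#' strictly below the threshold (open comparison), which is how the
#' divide-the-level formulation of the Bonferroni procedure is stated;
#' the multiply-the-p-value formulation in [adjust_pvalues()] rejects on
#' `adjusted <= alpha` (closed). The two disagree only when a p-value sits
#' exactly on the boundary.
#'
#' @param alpha Family-wise significance level in (0, 1).
#' @param n Number of tests (positive integer).
#' @return The threshold `alpha / n`.
#' @examples
#' bonferroni_threshold(0.05, 5)      # 0.01
#' bonferroni_threshold(0.05, 40000)  # 1.25e-06
#' @export
bonferroni_threshold <- function(alpha, n) {
  stopifnot(alpha > 0, alpha < 1, n >= 1)
  alpha / n
}

# Vector-level adjustment engine. `p` is a validated numeric vector; returns
# list(adjusted, rejected, params). Results are aligned with the input order.
#
# Sequential methods enforce monotone adjusted values (running maximum down
# the ranks for step-down, running minimum up from the largest p for step-up)
# so that "reject iff adjusted <= alpha" is exactly the sequential stop rule;
# ties in p then receive identical adjusted values automatically. All
# adjusted values are capped at 1: they are probabilities.
adjust_engine <- function(p, method, alpha = 0.05, fdr_level = alpha,
                          dependence = c("positive", "arbitrary"),
                          pi0 = NULL, pi0_estimator = "count_above_half") {
  dependence <- match.arg(dependence)
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- seq_len(n)
  unsort <- function(x) { out <- numeric(n); out[ord] <- x; out }

  if (method %in% c("bonferroni", "sidak")) {
    adj <- switch(method,
      bonferroni = pmin(1, n * p),
      sidak      = 1 - (1 - p)^n)
    return(list(adjusted = adj, rejected = adj <= alpha,
                params = list(alpha = alpha)))
  }

  if (method %in% c("holm", "hochberg", "hochberg_rank")) {
    adj_s <- switch(method,
      # step-down: rank k multiplied by (n - k + 1), running max downwards
      holm = pmin(1, cummax((n - k + 1) * ps)),
      # step-up: same multipliers, running min upward from the largest p
      hochberg = pmin(1, rev(cummin(rev((n - k + 1) * ps)))),
      # non-standard step-up variant: ascending rank k multiplied by k, so
      # the largest p is multiplied by n, the second largest by n - 1, ...
      hochberg_rank = pmin(1, rev(cummin(rev(k * ps)))))
    adj <- unsort(adj_s)
    params <- list(alpha = alpha)
    if (method == "hochberg_rank") params$standard <- FALSE
    return(list(adjusted = adj, rejected = adj <= alpha, params = params))
  }

  if (method %in% c("bh", "by")) {
    cn <- if (method == "by" && dependence == "arbitrary") sum(1 / k) else 1
    adj_s <- rev(cummin(rev(pmin(1, cn * (n / k) * ps))))
    # rejection by the critical-value rule: largest k with p_(k) strictly
    # below (k / (n * c(n))) * fdr_level; all ranks up to it are rejected
    crit <- (k / (n * cn)) * fdr_level
    hits <- which(ps < crit)
    kstar <- if (length(hits)) max(hits) else 0L
    rej <- logical(n)
    rej[ord] <- k <= kstar
    params <- list(fdr_level = fdr_level)
    if (method == "by") params$dependence <- dependence
    return(list(adjusted = unsort(adj_s), rejected = rej, params = params))
  }

  if (method == "qvalue") {
    if (is.null(pi0)) {
      pi0_fit <- pi0_engine(p, pi0_estimator)
      pi0 <- pi0_fit$value
    } else {
      pi0_estimator <- "supplied"
    }
    # S(t) at t = p_(j) counts every p <= p_(j), so tied p-values share S(t)
    s_at <- findInterval(ps, ps)
    fdr_s <- pmin(1, pi0 * n * ps / pmax(s_at, 1L))
    q_s <- rev(cummin(rev(fdr_s)))
    return(list(adjusted = unsort(q_s), rejected = unsort(q_s) <= fdr_level,
                params = list(fdr_level = fdr_level, pi0 = pi0,
                              pi0_estimator = pi0_estimator)))
  }

  abort(sprintf("unknown method '%s'; valid methods: %s",
                method, paste(mt_methods(), collapse = ", ")),
        class = "mt_usage_error")
}

#' Adjust p-values for multiple testing
#'
#' The package's central verb. Takes a data frame with a column of raw
#' p-values, applies one correction method, and returns the data with two new
#' columns: the adjusted value and a rejection flag. Methods:
#'
#' * `"bonferroni"` — single step, `min(1, n * p)`; controls the family-wise
#'   error rate (FWER) under any dependence.
#' * `"sidak"` — single step, `1 - (1 - p)^n`; exact FWER control under
#'   independence; always no larger than the Bonferroni value.
#' * `"holm"` — step-down: ascending rank k is multiplied by `n - k + 1`, a
#'   running maximum keeps adjusted values monotone; FWER control under any
#'   dependence, uniformly more powerful than Bonferroni.
#' * `"hochberg"` — step-up with the same multipliers, scanned from the
#'   largest p-value down (running minimum); at least as powerful as Holm;
#'   valid under independence or positive dependence.
#' * `"hochberg_rank"` — a non-standard step-up variant in which ascending
#'   rank k is multiplied by k (so the largest p-value is multiplied by n).
#'   It appears in some applied walkthroughs of the step-up idea; it is far
#'   more conservative than the standard Hochberg procedure and is provided
#'   for reproducing such walkthroughs. Flagged `standard = FALSE` in the
#'   result parameters.
#' * `"bh"` — Benjamini-Hochberg step-up FDR control at `fdr_level`:
#'   rejection finds the largest rank k with `p_(k) < (k/n) * fdr_level`
#'   (strict, see [bh_critical_values()]); adjusted values are
#'   `min over j >= k of min(1, (n/j) p_(j))`.
#' * `"by"` — Benjamini-Yekutieli: BH rescaled by `c(n)`. With
#'   `dependence = "positive"` (the default) `c(n) = 1` and the result is
#'   identical to BH; with `dependence = "arbitrary"`,
#'   `c(n) = sum_{i<=n} 1/i` guards FDR control under any dependence.
#' * `"qvalue"` — Storey q-values: the minimum estimated positive FDR over
#'   all rejection thresholds at which the test would be called significant.
#'   Uses a pi0 estimate (see [estimate_pi0()]); with `pi0 = 1` q-values
#'   equal the BH adjusted values exactly. The new column is named
#'   `q_value` instead of `p_adjusted`.
#'
#' @param data A data frame with a p-value column, a bare numeric vector, or
#'   a collection from [validate_pvalues()].
#' @param p,id Tidy-eval columns passed to [validate_pvalues()].
#' @param method One of the method names above.
#' @param alpha Significance level for the FWER methods (default 0.05).
#' @param fdr_level Target false discovery rate for `"bh"`, `"by"` and
#'   `"qvalue"` (defaults to `alpha`).
#' @param dependence For `"by"`: `"positive"` or `"arbitrary"`.
#' @param pi0 Optional known proportion of true nulls for `"qvalue"`;
#'   estimated from the data when `NULL`.
#' @param pi0_estimator Estimator used when `pi0` is `NULL`; see
#'   [estimate_pi0()].
#'
#' @return A tibble of class `"mt_adjust"` with columns `id`, `p`,
#'   `p_adjusted` (or `q_value`), `rejected`, carrying the method name,
#'   level and parameters as attributes. Use [tidy()] for a plain tibble,
#'   [glance()] for a one-row summary, and [autoplot()] to visualise.
#'
#' @examples
#' df <- data.frame(p = c(0.001, 0.016, 0.2, 0.8))
#' adjust_pvalues(df, method = "bonferroni")
#' adjust_pvalues(df, method = "bh", fdr_level = 0.05) |> glance()
#' @export
adjust_pvalues <- function(data, p = p, id = NULL,
                           method = mt_methods(),
                           alpha = 0.05, fdr_level = alpha,
                           dependence = c("positive", "arbitrary"),
                           pi0 = NULL,
                           pi0_estimator = c("count_above_half", "twice_mean_p")) {
  method <- match.arg(method)
  dependence <- match.arg(dependence)
  pi0_estimator <- match.arg(pi0_estimator)
  stopifnot(alpha > 0, alpha < 1, fdr_level > 0, fdr_level < 1)
  pv <- if (inherits(data, "mt_pvalues")) data
        else validate_pvalues(data, p = {{ p }}, id = {{ id }})
  fit <- adjust_engine(pv$p, method, alpha = alpha, fdr_level = fdr_level,
                       dependence = dependence, pi0 = pi0,
                       pi0_estimator = pi0_estimator)
  value_col <- if (method == "qvalue") "q_value" else "p_adjusted"
  out <- tibble(id = pv$id, p = pv$p)
  out[[value_col]] <- fit$adjusted
  out$rejected <- fit$rejected
  structure(out,
            class = c("mt_adjust", class(tibble())),
            method = method,
            alpha = alpha,
            params = fit$params)
}
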