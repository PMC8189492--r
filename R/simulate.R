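#' Generate synthetic p-values with ground-truth labels
#'
#' Draws m one-sided z-test p-values from a null/alternative mixture with
#' known truth, for studying the error control of correction methods. Test
#' statistics follow an equicorrelated Gaussian model:
#' `z_i = sqrt(rho) * Z_common + sqrt(1 - rho) * Z_i + effect * [alternative]`,
#' converted to upper-tail p-values under the standard normal null. With
#' `rho = 0` the null p-values are exactly uniform on \[0, 1\] and
#' independent; `rho > 0` induces the weak positive correlation typical of
#' co-regulated genes or linked markers. `round(m * pi0)` tests are true
#' nulls; the rest carry a mean shift of `effect` standard deviations.
#'
#' @param m Number of tests.
#' @param pi0 True proportion of null hypotheses in \[0, 1\] (default 1).
#' @param effect Mean shift of the alternative test statistics,
#'   nonnegative, in null standard deviations (default 0).
#' @param rho Equicorrelation of the test statistics in \[0, 0.9\]
#'   (default 0).
#' @param seed Optional integer seed; the same seed yields bit-identical
#'   output.
#' @return A tibble of class `"mt_truth"` with columns `id`, `p`,
#'   `is_null`, carrying the generator configuration as attribute
#'   `"config"`.
#' @examples
#' sim <- simulate_pvalues(1000, pi0 = 0.8, effect = 3, seed = 1)
#' estimate_pi0(sim)
#' @export
simulate_pvalues <- function(m, pi0 = 1, effect = 0, rho = 0, seed = NULL) {
  if (!is.numeric(pi0) || pi0 < 0 || pi0 > 1) {
    abort("pi0 must lie in [0, 1]", class = "mt_usage_error")
  }
  if (!is.numeric(rho) || rho < 0 || rho > 0.9) {
    abort("rho must lie in [0, 0.9]", class = "mt_usage_error")
  }
  stopifnot(m >= 1, effect >= 0)
  draw <- function() {
    m0 <- round(m * pi0)
    is_null <- c(rep(TRUE, m0), rep(FALSE, m - m0))
    z <- sqrt(rho) * rnorm(1) + sqrt(1 - rho) * rnorm(m) +
      effect * as.numeric(!is_null)
    tibble(id = sprintf("test_%d", seq_len(m)),
           p = pnorm(z, lower.tail = FALSE),
           is_null = is_null)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(out,
            class = c("mt_truth", class(tibble())),
            config = list(m = m, pi0 = pi0, effect = effect, rho = rho,
                          seed = seed))
}

# Rejection flags for one method on one vector of p-values at one level.
method_rejections <- function(p, method, level) {
  if (method %in% mt_fwer_methods()) {
    adjust_engine(p, method, alpha = level)$rejected
  } else {
    adjust_engine(p, method, fdr_level = level)$rejected
  }
}

#' Measure empirical error rates and power by Monte-Carlo simulation
#'
#' Runs `reps` independent replicates of [simulate_pvalues()], applies each
#' correction method to every replicate, and tallies per replicate the
#' number of true nulls rejected (V), the total rejections (R), whether at
#' least one false positive occurred (the FWER indicator), the false
#' discovery proportion V/R (defined as 0 when R = 0, matching FDR rather
#' than pFDR semantics), and the fraction of true alternatives rejected
#' (power). Means and Monte-Carlo standard errors are aggregated per method;
#' the pFDR column reports V/R averaged only over replicates with at least
#' one rejection.
#'
#' @inheritParams simulate_pvalues
#' @param methods Character vector of method names (see
#'   [adjust_pvalues()]).
#' @param level Significance level for FWER methods and target FDR for
#'   FDR methods (default 0.05).
#' @param reps Number of replicates (default 1000).
#' @return A tibble of class `"mt_performance"`, one row per method, with
#'   columns `method`, `reps`, `fwer`, `fwer_se`, `fdr`, `fdr_se`, `pfdr`,
#'   `power`, `power_se`, `mean_rejections`.
#' @examples
#' evaluate_methods(m = 50, pi0 = 0.8, effect = 3, reps = 100, seed = 1)
#' @export
evaluate_methods <- function(methods = c("bonferroni", "holm", "hochberg", "bh"),
                             m = 100, pi0 = 1, effect = 0, rho = 0,
                             level = 0.05, reps = 1000, seed = NULL) {
  bad <- setdiff(methods, mt_methods())
  if (length(bad) > 0L) {
    abort(sprintf("unknown method '%s'; valid methods: %s",
                  bad[1], paste(mt_methods(), collapse = ", ")),
          class = "mt_usage_error")
  }
  stopifnot(reps >= 1, level > 0, level < 1)
  run <- function() {
    per_rep <- lapply(seq_len(reps), function(r) {
      sim <- simulate_pvalues(m, pi0 = pi0, effect = effect, rho = rho)
      n_alt <- sum(!sim$is_null)
      rows <- lapply(methods, function(meth) {
        rej <- method_rejections(sim$p, meth, level)
        v <- sum(rej & sim$is_null)
        rr <- sum(rej)
        tibble(method = meth,
               v = v, r = rr,
               fwer_ind = as.numeric(v >= 1),
               fdp = if (rr > 0) v / rr else 0,
               fdp_pos = if (rr > 0) v / rr else NA_real_,
               power = if (n_alt > 0) sum(rej & !sim$is_null) / n_alt
                       else NA_real_)
      })
      bind_rows(rows)
    })
    bind_rows(per_rep)
  }
  raw <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mc_se <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    sd(x) / sqrt(length(x))
  }
  out <- raw |>
    group_by(.data$method) |>
    summarise(reps = dplyr::n(),
              fwer = mean(.data$fwer_ind),
              fwer_se = mc_se(.data$fwer_ind),
              fdr = mean(.data$fdp),
              fdr_se = mc_se(.data$fdp),
              pfdr = if (all(is.na(.data$fdp_pos))) NA_real_
                     else mean(.data$fdp_pos, na.rm = TRUE),
              power_se = mc_se(.data$power),
              power = if (all(is.na(.data$power))) NA_real_
                      else mean(.data$power, na.rm = TRUE),
              mean_rejections = mean(.data$r),
              .groups = "drop") |>
    dplyr::arrange(match(.data$method, methods))
  out <- out[, c("method", "reps", "fwer", "fwer_se", "fdr", "fdr_se",
                 "pfdr", "power", "power_se", "mean_rejections")]
  structure(out,
            class = c("mt_performance", class(tibble())),
            config = list(m = m, pi0 = pi0, effect = effect, rho = rho,
                          level = level, reps = reps, seed = seed))
}
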