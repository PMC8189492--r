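#' Tidy an adjustment result
#'
#' @param x An `"mt_adjust"` tibble from [adjust_pvalues()].
#' @param ... Unused.
#' @return A plain tibble with columns `id`, `p`, `p_adjusted` (or
#'   `q_value`), `rejected`, `method`.
#' @method tidy mt_adjust
#' @export
tidy.mt_adjust <- function(x, ...) {
  out <- as_tibble(unclass_mt(x))
  out$method <- attr(x, "method")
  out
}

#' One-row summary of an adjustment result
#'
#' @param x An `"mt_adjust"` tibble.
#' @param ... Unused.
#' @return A one-row tibble: `method`, `n`, `alpha` (or `fdr_level`),
#'   `n_rejected`, and `pi0` for q-values.
#' @method glance mt_adjust
#' @export
glance.mt_adjust <- function(x, ...) {
  params <- attr(x, "params")
  out <- tibble(method = attr(x, "method"),
                n = nrow(x),
                level = if (!is.null(params$fdr_level)) params$fdr_level
                        else attr(x, "alpha"),
                n_rejected = sum(x$rejected))
  if (!is.null(params$pi0)) {
    out$pi0 <- params$pi0
    out$pi0_estimator <- params$pi0_estimator
  }
  out
}

#' Tidy a performance table
#'
#' @param x An `"mt_performance"` tibble from [evaluate_methods()].
#' @param ... Unused.
#' @return The table as a plain tibble.
#' @method tidy mt_performance
#' @export
tidy.mt_performance <- function(x, ...) {
  as_tibble(unclass_mt(x))
}

#' One-row summary of a simulation study
#'
#' @param x An `"mt_performance"` tibble.
#' @param ... Unused.
#' @return A one-row tibble with the generator configuration and the number
#'   of methods compared.
#' @method glance mt_performance
#' @export
glance.mt_performance <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble(m = cfg$m, pi0 = cfg$pi0, effect = cfg$effect, rho = cfg$rho,
         level = cfg$level, reps = cfg$reps, n_methods = nrow(x))
}

unclass_mt <- function(x) {
  cls <- class(x)
  class(x) <- cls[!startsWith(cls, "mt_")]
  attr(x, "method") <- NULL
  attr(x, "params") <- NULL
  attr(x, "alpha") <- NULL
  attr(x, "config") <- NULL
  x
}

#' @export
print.mt_adjust <- function(x, ...) {
  params <- attr(x, "params")
  cat(sprintf("# Multiple-testing adjustment: %s (%s), %d of %d rejected\n",
              attr(x, "method"), format_params(params), sum(x$rejected),
              nrow(x)))
  print(as_tibble(unclass_mt(x)), ...)
  invisible(x)
}

#' @export
print.mt_recommendation <- function(x, ...) {
  cat(sprintf("Recommended method: %s (%s control)\n", x$method, x$family))
  path <- x$path[[1]]
  for (i in seq_len(nrow(path))) {
    cat(sprintf("  %s %s\n", path$question[i], path$answer[i]))
  }
  cat(strwrap(x$caveat, width = 72, prefix = "  "), sep = "\n")
  invisible(x)
}

#' Plot raw against adjusted p-values
#'
#' Scatter of adjusted value (or q-value) against raw p-value on log10
#' axes, coloured by rejection status, with the identity line and the
#' significance level for reference.
#'
#' @param object An `"mt_adjust"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mt_adjust
#' @export
autoplot.mt_adjust <- function(object, ...) {
  value_col <- if ("q_value" %in% names(object)) "q_value" else "p_adjusted"
  params <- attr(object, "params")
  level <- if (!is.null(params$fdr_level)) params$fdr_level
           else attr(object, "alpha")
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data[[value_col]],
                                   colour = .data$rejected)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_hline(yintercept = level, linetype = "dashed",
                        colour = "grey30") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "raw p-value",
                  y = gsub("_", " ", value_col),
                  colour = "rejected",
                  title = sprintf("%s adjustment (level %g)",
                                  attr(object, "method"), level))
}

#' Plot empirical error rates and power per method
#'
#' Dot-and-error-bar panels of empirical FWER, FDR and power per method,
#' with +/- 2 Monte-Carlo standard errors and the nominal level marked on
#' the error-rate panels.
#'
#' @param object An `"mt_performance"` tibble from [evaluate_methods()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mt_performance
#' @export
autoplot.mt_performance <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- tidy(object)
  long <- dplyr::bind_rows(
    tibble(method = df$method, metric = "FWER", value = df$fwer,
           se = df$fwer_se),
    tibble(method = df$method, metric = "FDR", value = df$fdr,
           se = df$fdr_se),
    tibble(method = df$method, metric = "power", value = df$power,
           se = df$power_se))
  ref <- tibble(metric = c("FWER", "FDR"), level = cfg$level)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$level),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(0, .data$value - 2 * .data$se),
                                          ymax = pmin(1, .data$value + 2 * .data$se))) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "empirical rate",
                  title = sprintf("m = %d, pi0 = %g, effect = %g, rho = %g, %d replicates",
                                  cfg$m, cfg$pi0, cfg$effect, cfg$rho,
                                  cfg$reps))
}
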