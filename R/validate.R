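#' Validate a collection of p-values
#'
#' Checks a set of raw p-values and returns them as a tidy two-column tibble
#' (`id`, `p`) that every other verb in the package accepts. Input order is
#' preserved. This is the package's universal input container: a p-value is a
#' unitless probability, so every value must lie in \[0, 1\] and be
#' non-missing.
#'
#' @param data A data frame holding a p-value column, or a bare numeric
#'   vector of p-values.
#' @param p Column holding the p-values when `data` is a data frame
#'   (tidy-eval; default `p`). Ignored for vector input.
#' @param id Optional column of unique identifiers (tidy-eval). When absent,
#'   ids `"test_1" ... "test_n"` are generated.
#'
#' @return A tibble with columns `id` (character) and `p` (double) and class
#'   `"mt_pvalues"`; `nrow()` is the number of tests.
#'
#' @examples
#' validate_pvalues(c(0.01, 0.5, 1.0))
#' validate_pvalues(data.frame(gene = c("a", "b"), p = c(0.2, 0.8)), p, gene)
#' @export
validate_pvalues <- function(data, p = p, id = NULL) {
  if (is.data.frame(data)) {
    pv <- eval_tidy(enquo(p), data)
    idq <- enquo(id)
    ids <- if (quo_is_null(idq)) NULL else as.character(eval_tidy(idq, data))
  } else {
    pv <- data
    ids <- names(data)
  }
  if (length(pv) == 0L) {
    abort("empty input: at least one p-value is required", class = "mt_data_error")
  }
  if (!is.numeric(pv)) {
    bad <- which(is.na(suppressWarnings(as.numeric(pv))))[1]
    if (is.na(bad)) bad <- 1L
    abort(sprintf("non-numeric p-value at index %d", bad), class = "mt_data_error")
  }
  if (anyNA(pv)) {
    abort(sprintf("missing p-value at index %d", which(is.na(pv))[1]),
          class = "mt_data_error")
  }
  out_of_range <- which(pv < 0 | pv > 1)
  if (length(out_of_range) > 0L) {
    abort(sprintf("p-value out of range at index %d (value %g)",
                  out_of_range[1], pv[out_of_range[1]]),
          class = "mt_data_error")
  }
  if (is.null(ids)) {
    ids <- sprintf("test_%d", seq_along(pv))
  } else if (anyDuplicated(ids)) {
    abort("ids must be unique", class = "mt_data_error")
  }
  if (length(ids) != length(pv)) {
    abort("ids and p-values must have the same length", class = "mt_data_error")
  }
  out <- tibble(id = ids, p = as.numeric(pv))
  class(out) <- c("mt_pvalues", class(out))
  out
}
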