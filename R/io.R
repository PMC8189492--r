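#' Read a p-value table from a CSV or TSV file
#'
#' Reads a delimited text file holding one p-value per row, with an optional
#' header and an optional identifier column, and returns a validated
#' collection (see [validate_pvalues()]). The delimiter is auto-detected
#' from the first non-blank line (tab wins over comma) unless given; blank
#' lines and `#` comment lines are skipped; row order is preserved. A header
#' is assumed when no field of the first line parses as a number.
#'
#' @param path Path to the file.
#' @param column Name of the p-value column when the file has a header;
#'   defaults to the first column whose values are all numeric.
#' @param delimiter Field delimiter; `NULL` (default) auto-detects.
#' @return An `"mt_pvalues"` tibble with columns `id` and `p`.
#' @export
read_pvalue_table <- function(path, column = NULL, delimiter = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "mt_data_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !grepl("^\\s*#", lines)
  rows <- lines[keep]
  line_no <- which(keep)
  if (length(rows) == 0L) {
    abort("empty input: file contains no data rows", class = "mt_data_error")
  }
  if (is.null(delimiter)) {
    delimiter <- if (grepl("\t", rows[1])) "\t" else ","
  }
  cells <- strsplit(rows, delimiter, fixed = TRUE)
  width <- max(lengths(cells))
  mat <- vapply(cells, function(x) { length(x) <- width; trimws(x) },
                character(width))
  mat <- if (width == 1L) matrix(mat, ncol = 1L) else t(mat)
  first_numeric <- suppressWarnings(as.numeric(mat[1, ]))
  has_header <- all(is.na(first_numeric))
  header <- if (has_header) mat[1, ] else sprintf("V%d", seq_len(width))
  if (has_header) {
    mat <- mat[-1, , drop = FALSE]
    line_no <- line_no[-1]
  }
  if (nrow(mat) == 0L) {
    abort("empty input: file contains a header but no data rows",
          class = "mt_data_error")
  }
  numeric_col <- apply(mat, 2, function(x)
    !anyNA(suppressWarnings(as.numeric(x))) && !any(toupper(x) == "NA"))
  if (!is.null(column)) {
    p_idx <- match(column, header)
    if (is.na(p_idx)) {
      abort(sprintf("column '%s' not found (columns: %s)",
                    column, paste(header, collapse = ", ")),
            class = "mt_data_error")
    }
  } else {
    p_idx <- which(numeric_col)[1]
    if (is.na(p_idx)) {
      # no fully-numeric column: report the first offending cell by file row
      col_guess <- if (width == 1L) 1L else which(!numeric_col)[width]
      bad <- which(is.na(suppressWarnings(as.numeric(mat[, col_guess]))) |
                     toupper(mat[, col_guess]) == "NA")[1]
      abort(sprintf("no numeric p-value column found; unparseable cell at row %d",
                    line_no[bad]), class = "mt_data_error")
    }
  }
  p_raw <- mat[, p_idx]
  bad <- which(is.na(suppressWarnings(as.numeric(p_raw))) |
                 toupper(p_raw) == "NA")
  if (length(bad) > 0L) {
    abort(sprintf("unparseable p-value '%s' at row %d",
                  p_raw[bad[1]], line_no[bad[1]]), class = "mt_data_error")
  }
  pvals <- as.numeric(p_raw)
  id_idx <- setdiff(which(!numeric_col), p_idx)[1]
  ids <- if (!is.na(id_idx)) mat[, id_idx] else NULL
  collection <- tryCatch(
    if (is.null(ids)) validate_pvalues(pvals)
    else validate_pvalues(tibble(id = ids, p = pvals), p = p, id = id),
    mt_data_error = function(e) {
      idx <- suppressWarnings(as.integer(sub(".*index (\\d+).*", "\\1",
                                             conditionMessage(e))))
      if (!is.na(idx)) {
        abort(sprintf("%s (file row %d)", conditionMessage(e), line_no[idx]),
              class = "mt_data_error")
      }
      stop(e)
    })
  collection
}

format_params <- function(params) {
  params <- params[!vapply(params, is.null, logical(1))]
  if (length(params) == 0L) return("")
  paste(sprintf("%s=%s", names(params),
                vapply(params, function(v) format(v, digits = 15), "")),
        collapse = ";")
}

#' Write adjustment or simulation results to CSV
#'
#' Writes an `"mt_adjust"` result as CSV with columns `id`, `p_raw`,
#' `adjusted` (or `q_value`), `rejected`, `method`, `parameters`, preceded
#' by `#` comment lines recording the method and its parameters (for
#' q-values, pi0 and the estimator used). Numeric values are written with
#' 15 significant digits, so a write/read round trip preserves them beyond
#' 12 significant digits. An `"mt_performance"` table is written as-is with
#' a configuration comment header. Plain data frames are written as plain
#' CSV.
#'
#' @param result An `"mt_adjust"` tibble, `"mt_performance"` tibble, or
#'   any data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(result, path) {
  con <- tryCatch(file(path, "w"), error = function(e)
    abort(sprintf("cannot write to '%s'", path), class = "mt_data_error"))
  on.exit(close(con))
  if (inherits(result, "mt_adjust")) {
    method <- attr(result, "method")
    params <- attr(result, "params")
    value_col <- if ("q_value" %in% names(result)) "q_value" else "adjusted"
    writeLines(c(sprintf("# method: %s", method),
                 sprintf("# parameters: %s", format_params(params))), con)
    out <- data.frame(id = result$id,
                      p_raw = format(result$p, digits = 15, trim = TRUE),
                      value = format(result[[3]], digits = 15, trim = TRUE),
                      rejected = result$rejected,
                      method = method,
                      parameters = format_params(params))
    names(out)[3] <- value_col
    utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  } else if (inherits(result, "mt_performance")) {
    cfg <- attr(result, "config")
    writeLines(sprintf("# config: %s", format_params(cfg)), con)
    utils::write.csv(as.data.frame(result), con, row.names = FALSE,
                     quote = FALSE)
  } else {
    utils::write.csv(as.data.frame(result), con, row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}
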