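#' Recommend a multiple-testing correction method
#'
#' Walks a small decision tree over four study characteristics and returns
#' one implemented method together with the path of questions traversed.
#' The encoded rules:
#'
#' 1. If false positives cannot be tolerated (e.g. a confirmatory clinical
#'    endpoint), a family-wise error rate method is required regardless of
#'    the number of tests: Holm, which is valid under any dependence and
#'    uniformly better than Bonferroni.
#' 2. Otherwise, confirmatory analyses over a modest family (up to
#'    `small_n` tests — on the order of a couple of dozens to a couple of
#'    hundreds, as in candidate-gene studies) also stay in the FWER family:
#'    Hochberg when tests are independent (more powerful), Holm when they
#'    may be dependent.
#' 3. Exploratory analyses, or any family larger than `small_n`, move to
#'    false-discovery-rate control: Benjamini-Hochberg (with q-values as the
#'    per-test FDR measure) under independence or weak positive correlation,
#'    and Benjamini-Yekutieli when dependence of unknown form must be
#'    guarded against.
#'
#' The tree is total: every combination of answers yields exactly one
#' method implemented by [adjust_pvalues()].
#'
#' @param exploratory Is the analysis exploratory (hypothesis-generating
#'   screening) rather than confirmatory (pre-registered hypotheses)?
#' @param n_tests Number of simultaneous tests.
#' @param dependent Might the tests be correlated in an unknown way?
#' @param tolerate_false_positives Is a controlled proportion of false
#'   discoveries acceptable in exchange for power?
#' @param small_n Upper bound on what counts as a small family
#'   (default 300).
#' @return A one-row tibble of class `"mt_recommendation"` with columns
#'   `method`, `family` (`"fwer"` or `"fdr"`), `caveat`, and a list-column
#'   `path` of the (question, answer) pairs traversed.
#' @examples
#' recommend_method(exploratory = TRUE, n_tests = 20000,
#'                  dependent = FALSE, tolerate_false_positives = TRUE)
#' @export
recommend_method <- function(exploratory, n_tests, dependent,
                             tolerate_false_positives, small_n = 300) {
  stopifnot(is.logical(exploratory), is.logical(dependent),
            is.logical(tolerate_false_positives), n_tests >= 1, small_n >= 1)
  path <- list()
  step <- function(question, answer) {
    path[[length(path) + 1L]] <<- tibble(question = question,
                                         answer = as.character(answer))
  }
  step("exploratory analysis?", exploratory)
  step("tolerate some false positives?", tolerate_false_positives)
  if (!tolerate_false_positives) {
    method <- "holm"
    family <- "fwer"
    caveat <- paste("Family-wise error control chosen because false",
                    "positives are intolerable; Holm is valid under any",
                    "dependence and never worse than Bonferroni. With many",
                    "tests expect substantial loss of power.")
  } else {
    small <- n_tests <= small_n
    step(sprintf("number of tests at most %d?", small_n), small)
    if (!exploratory && small) {
      step("tests independent?", !dependent)
      if (dependent) {
        method <- "holm"
        caveat <- paste("Confirmatory testing of a small family with",
                        "possible dependence: Holm keeps family-wise error",
                        "control without independence assumptions.")
      } else {
        method <- "hochberg"
        caveat <- paste("Confirmatory testing of a small family of",
                        "independent tests: the step-up Hochberg procedure",
                        "rejects at least as much as Holm.")
      }
      family <- "fwer"
    } else {
      step("tests independent or weakly positively correlated?", !dependent)
      family <- "fdr"
      if (dependent) {
        method <- "by"
        caveat <- paste("Dependence of unknown form: Benjamini-Yekutieli",
                        "controls the FDR under arbitrary dependence, at a",
                        "log(n) cost in power; the PFP is an alternative",
                        "when a per-experiment false-positive proportion is",
                        "wanted.")
      } else {
        method <- "bh"
        caveat <- paste("Large-scale or exploratory screening:",
                        "Benjamini-Hochberg FDR control balances discovery",
                        "against false positives; report per-test q-values",
                        "alongside.")
      }
    }
  }
  out <- tibble(method = method, family = family, caveat = caveat,
                path = list(bind_rows(path)))
  class(out) <- c("mt_recommendation", class(out))
  out
}
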