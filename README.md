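# padjustr

Tidy multiple hypothesis testing correction for R.

Screening experiments — differential expression, GWAS, metabolite panels,
ecological surveys — run hundreds to tens of thousands of significance tests
at once. At a per-test level of α = 0.05, testing 20,000 genes in which
every null is true still yields about 1000 "significant" results by chance
alone. `padjustr` implements the standard corrections for this multiplicity
problem as data-frame-first verbs that pipe, plot, and round-trip through
CSV, plus a Monte-Carlo harness that demonstrates each method's error
guarantee on synthetic data with known ground truth.

## Methods

For n tests with ordered p-values p₍₁₎ ≤ … ≤ p₍ₙ₎:

| method | adjusted value | controls |
|---|---|---|
| `bonferroni` | min(1, n·pᵢ) | FWER, any dependence |
| `sidak` | 1 − (1 − pᵢ)ⁿ | FWER, independence |
| `holm` | step-down: rank k × (n − k + 1), running max | FWER, any dependence |
| `hochberg` | step-up: rank k × (n − k + 1), running min from the top | FWER, independence / positive dependence |
| `hochberg_rank` | non-standard step-up with multiplier k (the largest p × n); reproduces some applied walkthroughs, flagged `standard = FALSE` | — |
| `bh` | Benjamini–Hochberg: min over j ≥ k of min(1, (n/j)·p₍ⱼ₎); rejection via critical values (k/n)·q | FDR, independence / positive dependence |
| `by` | Benjamini–Yekutieli: BH × c(n), c(n) = Σ 1/i | FDR, arbitrary dependence |
| `qvalue` | Storey q-value: min over thresholds t ≥ pᵢ of π̂₀·m·t / S(t) | positive FDR |

Here FWER = family-wise error rate P(at least one false positive) =
1 − (1 − α_PC)^C (see `fwer()`); FDR = E[V/R], the expected proportion of
false discoveries among discoveries. π₀ — the proportion of true nulls —
is estimated by `estimate_pi0()` as either (2/n)·#{pᵢ > 0.5} or twice the
mean p-value, clamped into [1/n, 1]. `storey_fdr()`, `pfp_estimate()` and
`fdr_curve()` expose the threshold-wise positive-FDR estimate
π₀·m·t / S(t), and `recommend_method()` encodes a decision tree
(exploratory vs confirmatory, family size, dependence, tolerance for false
positives) that names one of the implemented methods.

## Worked example

```r
library(padjustr)

df  <- read_pvalue_table(system.file("extdata", "example_pvalues.csv",
                                     package = "padjustr"))
res <- adjust_pvalues(df, method = "bh", fdr_level = 0.05)
res
#> # Multiple-testing adjustment: bh (fdr_level=0.05), 2 of 10 rejected
#> # A tibble: 10 × 4
#>    id           p p_adjusted rejected
#>    <chr>    <dbl>      <dbl> <lgl>
#>  1 gene_1  0.0001     0.001  TRUE
#>  2 gene_2  0.0012     0.006  TRUE
#>  3 gene_3  0.016      0.0525 FALSE
#>  4 gene_4  0.021      0.0525 FALSE
#>  5 gene_5  0.048      0.096  FALSE
#>  ...
glance(qvalues(df))
#> # A tibble: 1 × 6
#>   method     n level n_rejected   pi0 pi0_estimator
#> 1 qvalue    10  0.05          4   0.6 count_above_half
```

At FDR 5%, only the two smallest p-values survive: calling `gene_1` and
`gene_2` significant carries an estimated 0.6% false-discovery burden
(their largest adjusted value), whereas the raw 0.05 cut-off would have
kept five genes and, at these ranks, a much higher one. The q-value run
additionally estimates that 60% of the ten tests are true nulls and finds
four tests with q ≤ 0.05 (π̂₀ < 1 makes q-values smaller than BH adjusted
values).

The simulation harness measures error control directly:

```r
evaluate_methods(c("bonferroni", "holm", "hochberg", "bh"),
                 m = 200, pi0 = 0.8, effect = 3, reps = 1000, seed = 1) |>
  autoplot()
```

## Command line

```sh
inst/cli/padjustr adjust --method bh --fdr-level 0.05 \
    --input pvalues.csv --output adjusted.csv
inst/cli/padjustr simulate --m 200 --pi0 0.8 --effect 3 --seed 7 --output perf.csv
inst/cli/padjustr recommend --exploratory --independent --tolerant --n-tests 20000
```

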