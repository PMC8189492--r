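---
title: "Multiple testing correction: models, choices and guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple testing correction: models, choices and guarantees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(padjustr)
```

## The problem

Each individual significance test run at level $\alpha$ admits a false
positive with probability $\alpha$ under its null. Run $C$ tests and the
probability of at least one false positive — the family-wise error rate —
grows as

$$\alpha_{FW} = 1 - (1 - \alpha_{PC})^C,$$

which `fwer()` computes: at $\alpha_{PC} = 0.05$, twenty independent tests
already carry a 64% chance of some false positive, and a 20,000-gene screen
under a complete null is expected to produce
`expected_false_positives(0.05, 20000)` = 1000 spurious hits. Every
procedure in this package trades power against some formal control of this
multiplicity: either of the FWER itself, or of the false discovery rate
$\mathrm{FDR} = E[V/R]$, the expected fraction of rejections $R$ that are
false rejections $V$.

## The procedures and their numerical conventions

All methods operate on the ascending order statistics
$p_{(1)} \le \dots \le p_{(n)}$ and report results in the input order.

**Single-step.** Bonferroni multiplies every p-value by $n$;
Šidák uses $1-(1-p)^n$, which is exact for independent tests and always no
larger than the Bonferroni value. Both are capped at 1 — adjusted p-values
are probabilities, and the cap is applied throughout the package.

**Step-down (Holm).** Rank $k$ receives multiplier $n-k+1$; testing
proceeds from the smallest p-value and stops at the first non-rejection.
We store adjusted values with a *running maximum* down the ranks so that
"reject iff adjusted $\le \alpha$" is exactly the sequential stop rule.
A useful consequence: tied raw p-values automatically share one adjusted
value, and rejection regions are always contiguous in rank.

**Step-up (Hochberg).** Same multipliers, scanned from the largest
p-value; the first significant rank drags every smaller p-value along. The
stored adjusted values carry a *running minimum* upward, making the closed
test equivalent again. Two variants are provided:

* `hochberg` — the standard procedure: ascending rank $k$ is multiplied
  by $n-k+1$, so the largest p-value keeps multiplier 1.
* `hochberg_rank` — a variant seen in applied walkthroughs of the step-up
  idea in which ascending rank $k$ is multiplied by $k$, i.e. the largest
  p-value is multiplied by $n$, the second largest by $n-1$, and so on.
  This is dramatically more conservative than the standard procedure and
  is **not** the Hochberg (1988) method; it is included, flagged
  `standard = FALSE`, so that published walkthroughs using those
  multipliers can be reproduced and compared. Because its multipliers
  increase with rank, tied p-values may receive distinct (though still
  monotone) adjusted values — the one place where the tie-equality
  guarantee does not apply.

**Benjamini–Hochberg.** Rank-wise critical values $(k/n)\,q$ at target FDR
$q$; the procedure finds the *largest* rank whose p-value is strictly below
its critical value and rejects it and all smaller p-values. Two boundary
conventions coexist deliberately, following how each rule is usually
worded: the critical-value comparison is strict (`<`), while rejection by
adjusted value elsewhere in the package uses closed `\le`. The two differ
only when a p-value lands exactly on a boundary — measure zero for
continuous statistics, and documented here because crafted inputs can hit
it. BH adjusted values are $\min_{j \ge k}\min(1, (n/j)\,p_{(j)})$.

**Benjamini–Yekutieli.** BH rescaled by $c(n)$: under positive dependence
$c(n) = 1$ (the output is then identical to BH by construction); under
arbitrary dependence $c(n) = \sum_{i=1}^n 1/i$, with critical values
divided and adjusted values multiplied by $c(n)$.

**Storey's positive FDR, PFP and q-values.** At a rejection threshold $t$,
the estimated positive FDR is $\min(1,\ \hat\pi_0\, m\, t / S(t))$ with $m$
the total number of tests and $S(t)$ the number of p-values at or below
$t$. We read $m$ as the *total* test count — the convention that makes the
$\hat\pi_0 = 1$ case reduce exactly to BH; with $S(t) = 0$ the quantity is
undefined (the "positive" in pFDR) and `storey_fdr()` errors. The PFP
(proportion of false positives, $E(V)/E(R)$ with numerator and denominator
estimated separately) uses the only estimators constructible from these
quantities, $\hat V = \hat\pi_0 m t$ and $\hat R = S(t)$, and therefore
coincides numerically with the pFDR here; it is kept as a separate verb
because the error measures are conceptually distinct. The q-value of test
$i$ is $\min_{t \ge p_i} \widehat{\mathrm{FDR}}(t)$; since the minimum over
thresholds is attained at observed p-values, the implementation evaluates
only those (a cumulative minimum from the largest p down), not a
continuous grid.

**$\pi_0$ estimation.** Two estimators, both reading the upper tail of the
p-value mixture where alternatives are rare: $(2/n)\,\#\{p_i > 0.5\}$
(`count_above_half`, the default) and $2\,\bar p$ (`twice_mean_p`). Both
are clamped into $[1/n, 1]$: $\pi_0$ is a proportion, and the $1/n$ floor
prevents a zero estimate from zeroing every q-value. Both are biased
upward when alternatives are not stochastically small; that conservatism
inflates q-values rather than anti-conservatively shrinking them.

## Dominance structure

On any fixed input the rejection sets nest:
Bonferroni $\subseteq$ Holm $\subseteq$ Hochberg $\subseteq$ BH
(the last because $n/j \le n-j+1$ for every rank $j$), and Šidák-adjusted
values never exceed Bonferroni ones. The property suite asserts this
per-input on random draws, and the simulation harness asserts it per
replicate; the corresponding power ordering follows automatically.

## The synthetic-data generator

`simulate_pvalues()` draws test statistics from a one-sided z-test model,

$$z_i = \sqrt{\rho}\,Z_{\mathrm{common}} + \sqrt{1-\rho}\,Z_i +
\mathrm{effect}\cdot \mathbf{1}[\text{alternative}],$$

with upper-tail p-values under the standard normal null;
$\mathrm{round}(m\pi_0)$ tests are true nulls. This is the simplest model
with an exactly uniform null, a single tunable effect size (in null
standard deviations), and a single positive-dependence parameter (the
equicorrelation $\rho$, capped at 0.9). Defaults used by the test suite
and the acceptance script, chosen once as representative of a moderate
screening study: a complete-null family of $m = 100$ over 2000 replicates
for FWER checks; $m = 200$, $\pi_0 = 0.8$, effect $= 3$, 1000 replicates,
with $\rho \in \{0, 0.2\}$, for FDR checks ($\rho = 0.2$ standing in for
the weak positive correlation typical of co-expressed genes or linked
markers); $m = 5000$ over 50 replicates for $\pi_0$ recovery. These sizes
keep the full suite to a couple of minutes on one CPU while leaving
Monte-Carlo standard errors small relative to the levels being checked.

What the generator does *not* emulate: heavy-tailed or discrete test
statistics, block or negative dependence, composite nulls, or effect-size
heterogeneity. Passing error-control checks under this model therefore
demonstrates correctness of the procedures' arithmetic and their behaviour
under the stated assumptions — not robustness on any particular real data
set.

The per-replicate false discovery proportion uses the convention
$V/R := 0$ when $R = 0$ (FDR semantics); the conditional mean given
$R > 0$ is reported separately as the pFDR column.

## The recommender

`recommend_method()` encodes an explicit decision table — an
interpretation, versioned here, of the questions practitioners are told to
ask. In order: (1) if false positives are intolerable, stay with FWER
control regardless of family size, and use Holm, which is assumption-free
and dominates Bonferroni; (2) confirmatory analyses over at most `small_n`
tests (default 300, "a couple of dozens to a couple of hundreds") also
stay with FWER — Hochberg under independence, Holm otherwise; (3)
exploratory or large families move to FDR control — BH (reported with
q-values) under independence or weak positive correlation, BY under
dependence of unknown form. Every answer combination maps to exactly one
implemented method, and the returned object carries the traversed path.

## Numerical and interface choices

* Elementary arithmetic only; no tolerances are applied when comparing
  adjusted values to levels. Package tests use `expect_equal()` with its
  default `1e-8`-scale tolerance (tighter, `1e-12`, where round-trips are
  asserted).
* `adjust_pvalues()` rejects at `adjusted <= alpha` (closed);
  `bonferroni_threshold()` documents the open `p < alpha/n` convention of
  the divide-the-level formulation.
* Ties: a stable sort plus the running max/min guarantees identical
  adjusted values for identical p-values (except `hochberg_rank`, above).
* Degenerate inputs: empty collections, p-values outside $[0,1]$, missing
  values and duplicate ids are rejected at validation with the offending
  index; $S(t) = 0$ makes positive-FDR quantities an error, while
  `fdr_curve()` reports `NA` there so a whole curve can still be drawn.
* CSV output writes 15 significant digits so values survive a write/read
  round trip beyond 12 digits; q-value files carry $\hat\pi_0$ and the
  estimator name in `#` comment headers.
* The command-line tool (`inst/cli/padjustr`) is a thin wrapper over the
  exported verbs — identical numbers by construction — with exit codes 0
  (success), 1 (usage error), 2 (data error).

## Known limitations

Local FDR (which needs a density estimate under the alternative) and
covariate-aware FDR procedures are out of scope. The `hochberg_rank`
variant should not be used for inference; it exists for comparison. The
$\pi_0$ estimators assume alternatives concentrate below 0.5; with weak
effects they drift toward 1, which is conservative but costs q-value
power.
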