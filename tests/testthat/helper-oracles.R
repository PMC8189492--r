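# Brute-force reference implementations of the sequential procedures,
# written as literal transcriptions of the stop rules. Deliberately slow
# (explicit loops, O(n^2) scans) and independent of the package internals.

# Step-down: examine p-values from smallest to largest; rank k is multiplied
# by (n - k + 1); stop at the first non-rejection. Adjusted values carry a
# running maximum so they are monotone in p.
oracle_holm <- function(p, alpha = 0.05) {
  n <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(n)
  rej_sorted <- logical(n)
  running <- 0
  stopped <- FALSE
  for (k in seq_len(n)) {
    running <- max(running, (n - k + 1) * p[ord][k])
    adj_sorted[k] <- min(1, running)
    if (!stopped && adj_sorted[k] <= alpha) {
      rej_sorted[k] <- TRUE
    } else {
      stopped <- TRUE  # once a rank fails, every larger rank fails
    }
  }
  out <- list(adjusted = numeric(n), rejected = logical(n))
  out$adjusted[ord] <- adj_sorted
  out$rejected[ord] <- rej_sorted
  out
}

# Step-up: examine p-values from largest to smallest with multipliers
# (n - k + 1) on ascending rank k; the first significant product rejects
# that test and every smaller p-value. Adjusted values carry a running
# minimum downward from the largest p.
oracle_hochberg <- function(p, alpha = 0.05, multiplier = c("standard", "rank")) {
  multiplier <- match.arg(multiplier)
  n <- length(p)
  ord <- order(p)
  mult <- if (multiplier == "standard") (n - seq_len(n) + 1) else seq_len(n)
  adj_sorted <- numeric(n)
  rej_sorted <- logical(n)
  running <- Inf
  hit <- FALSE
  for (k in rev(seq_len(n))) {
    running <- min(running, mult[k] * p[ord][k])
    adj_sorted[k] <- min(1, running)
    if (!hit && adj_sorted[k] <= alpha) hit <- TRUE
    rej_sorted[k] <- hit  # all smaller p-values are declared significant
  }
  out <- list(adjusted = numeric(n), rejected = logical(n))
  out$adjusted[ord] <- adj_sorted
  out$rejected[ord] <- rej_sorted
  out
}

# Benjamini-Hochberg by direct enumeration: critical value (k/n) * level,
# k* = largest rank with p_(k) strictly below it; adjusted value at rank k
# is the minimum over j >= k of min(1, (n/j) p_(j)), computed by a double
# loop.
oracle_bh <- function(p, level = 0.05, cn = 1) {
  n <- length(p)
  ord <- order(p)
  ps <- p[ord]
  kstar <- 0L
  for (k in seq_len(n)) {
    if (ps[k] < (k / (n * cn)) * level) kstar <- k
  }
  adj_sorted <- numeric(n)
  for (k in seq_len(n)) {
    adj_sorted[k] <- min(vapply(k:n, function(j) min(1, cn * (n / j) * ps[j]),
                                numeric(1)))
  }
  out <- list(adjusted = numeric(n), rejected = logical(n))
  out$adjusted[ord] <- adj_sorted
  out$rejected[ord] <- seq_len(n) <= kstar
  out
}

# q-values by exhaustive search: for each test, the minimum over every
# observed threshold t >= p_i of the capped positive-FDR estimate
# pi0 * m * t / #{p <= t}.
oracle_qvalue <- function(p, pi0 = 1) {
  m <- length(p)
  vapply(p, function(pi) {
    ts <- p[p >= pi]
    min(vapply(ts, function(t) min(1, pi0 * m * t / sum(p <= t)), numeric(1)))
  }, numeric(1))
}

# Random p-value vectors for property tests: mixes smooth uniforms, spiked
# small values, and (optionally) deliberate ties. Tie-free draws are used
# for the cross-method dominance checks, where a p-value landing exactly on
# a rejection boundary would probe the documented open-vs-closed comparison
# difference rather than the dominance property itself.
random_pvalues <- function(n, ties = TRUE) {
  style <- sample(if (ties) 3 else 2, 1)
  p <- switch(style,
              runif(n),
              c(runif(ceiling(n / 2), 0, 0.05), runif(floor(n / 2)))[seq_len(n)],
              round(runif(n), 2))  # coarse grid forces ties
  sample(p)
}
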