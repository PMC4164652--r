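# Independent oracles, deliberately naive: every expected value asserted
# against the package is recomputed here from first principles.

`%||%` <- function(a, b) if (is.null(a)) b else a

# KS distance via empirical CDFs evaluated at every pooled data point.
oracle_ks <- function(a, b) {
  xs <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(xs) - ecdf(b)(xs)))
}

# Exhaustive max-cut scan: recompute the KS distance naively at every
# admissible cut, smallest-position tie-break.
oracle_max_cut <- function(x, l0) {
  n <- length(x)
  ts <- l0:(n - l0)
  d <- vapply(ts, function(t) oracle_ks(x[1:t], x[(t + 1):n]), numeric(1))
  i <- which.max(d) # first maximum = smallest t
  list(cut = ts[i], d_max = d[i])
}

# Permutation estimate of the two-sample KS p-value.
oracle_perm_ks_p <- function(a, b, n_perm = 10000) {
  pooled <- c(a, b)
  na <- length(a)
  d0 <- oracle_ks(a, b)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (ks_distance(pooled[idx], pooled[-idx]) >= d0 - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Mann-Whitney AUC: average ranks of the positive class.
oracle_auc_mw <- function(values, labels) {
  r <- rank(values)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Type-7 quantile by hand: linear interpolation of the order statistics.
oracle_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  one <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    if (lo >= n) return(x[n])
    x[lo] + (h - lo) * (x[lo + 1] - x[lo])
  }
  c(q1 = one(0.25), median = one(0.5), q3 = one(0.75))
}

# A small critical curve calibrated once per test run for fast small-l0
# segmentation tests.
small_curve <- local({
  cache <- list()
  function(alpha = 0.01) {
    key <- as.character(alpha)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- calibrate_critical_curve(
        c(40L, 80L, 160L, 320L, 640L), alpha = alpha,
        l0 = 10L, n_null = 1000L, seed = 99L
      )
    }
    cache[[key]]
  }
})
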