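#' Per-subject quantifiers from a segmentation
#'
#' Reduces a segmentation to the subject-level screening features: the mean
#' patch length `mean_L` (beats), the mean local variance `mean_var`
#' (mmHg^2), and the mean local mean `mean_mu` (mmHg).  By default these are
#' unweighted means over patches; `weighted = TRUE` switches to beat-weighted
#' means (each patch weighted by its length).
#'
#' @param segmentation An `sbp_segmentation` (non-empty).
#' @param a_max Normalized spectral peak from [compute_amax()], if available.
#' @param subject_id,group,ahi Subject metadata carried through to the
#'   feature row.
#' @param weighted Beat-weighted instead of per-patch means.
#' @return A one-row tibble: `subject_id`, `group`, `ahi`, `n_segments`,
#'   `mean_L`, `mean_var`, `mean_mu`, `a_max`.
#' @export
subject_features <- function(segmentation, a_max = NA_real_,
                             subject_id = NA_character_, group = NA_character_,
                             ahi = NA_real_, weighted = FALSE) {
  check_segmentation(segmentation)
  if (nrow(segmentation) == 0L) abort("segmentation has no segments")
  w <- if (weighted) segmentation$length else rep(1, nrow(segmentation))
  tibble::tibble(
    subject_id = as.character(subject_id),
    group = as.character(group),
    ahi = as.numeric(ahi),
    n_segments = nrow(segmentation),
    mean_L = sum(w * segmentation$length) / sum(w),
    mean_var = sum(w * segmentation$variance) / sum(w),
    mean_mu = sum(w * segmentation$mean) / sum(w),
    a_max = as.numeric(a_max)
  )
}

#' Complementary cumulative distribution of segment lengths
#'
#' `P(L >= l)` evaluated at each distinct observed length, for one subject or
#' for a pooled group (concatenate the lengths before calling).
#'
#' @param lengths Integer/numeric vector of segment lengths (>= 1 value), or
#'   a segmentation tibble with a `length` column.
#' @return A tibble with columns `length` and `ccdf`, `ccdf` non-increasing
#'   and equal to 1 at the minimum length.
#' @export
length_ccdf <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (!length(lengths)) abort("need at least one length")
  l <- sort(unique(lengths))
  n <- length(lengths)
  ccdf <- vapply(l, function(x) sum(lengths >= x) / n, numeric(1))
  tibble::tibble(length = l, ccdf = ccdf)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares two samples (e.g. per-subject `mean_L` of an apneic group vs the
#' control group, or pooled segment lengths).  `D` is the pooled-CDF
#' supremum distance of [ks_distance()]; the p-value uses the exact two-sample
#' null distribution when feasible (no ties and `n_a * n_b < 10^4` — this is
#' the permutation distribution) and otherwise the asymptotic Kolmogorov
#' distribution with effective size `n_a * n_b / (n_a + n_b)`.
#'
#' @param a,b Numeric samples of size >= 2.
#' @param method `"auto"` (default), `"exact"`, or `"asymptotic"`.
#' @return One-row tibble: `d`, `p_value`, `n_a`, `n_b`, `method`.
#' @export
ks_two_sample <- function(a, b, method = c("auto", "exact", "asymptotic")) {
  method <- match.arg(method)
  if (length(a) < 2L || length(b) < 2L) abort("both samples need size >= 2")
  d <- ks_distance(a, b)
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- switch(method,
    auto = !has_ties && length(a) * length(b) < 10000,
    exact = TRUE,
    asymptotic = FALSE
  )
  if (use_exact && has_ties) {
    warn("ties present; falling back to the asymptotic p-value")
    use_exact <- FALSE
  }
  p <- suppressWarnings(ks.test(a, b, exact = use_exact)$p.value)
  tibble::tibble(d = d, p_value = p, n_a = length(a), n_b = length(b),
                 method = if (use_exact) "exact" else "asymptotic")
}

#' Quartiles by linear interpolation of the empirical CDF
#'
#' @param values Numeric vector (>= 1 value).
#' @return Named numeric vector `c(q1, median, q3)` (R's type-7 quantiles).
#' @export
quartiles3 <- function(values) {
  if (!length(values)) abort("need at least one value")
  setNames(quantile(values, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE),
           c("q1", "median", "q3"))
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3) with nonzero
#'   variance.
#' @return `r` in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("Pearson correlation undefined for zero-variance input")
  cor(x, y, method = "pearson")
}

#' Group-level comparisons of a per-subject feature
#'
#' Runs the two-sample KS test of each apneic group (HT, NT) against the
#' control group (C) for one feature column.
#'
#' @param features Feature tibble (one row per subject) with a `group`
#'   column.
#' @param feature Name of the feature column (string).
#' @param method Passed to [ks_two_sample()].
#' @return Tibble with one row per comparison: `feature`, `comparison`, `d`,
#'   `p_value`.
#' @export
group_ks_tests <- function(features, feature, method = "auto") {
  ctrl <- features[[feature]][features$group == "C"]
  purrr::map_dfr(intersect(c("HT", "NT"), unique(features$group)), function(g) {
    x <- features[[feature]][features$group == g]
    if (length(x) < 2L || length(ctrl) < 2L) {
      warn(sprintf("%s vs C needs >= 2 subjects per group; reporting NA", g))
      return(tibble::tibble(feature = feature, comparison = paste0(g, " vs C"),
                            d = NA_real_, p_value = NA_real_))
    }
    res <- ks_two_sample(x, ctrl, method = method)
    tibble::tibble(feature = feature, comparison = paste0(g, " vs C"),
                   d = res$d, p_value = res$p_value)
  })
}

#' Plot segment-length CCDFs
#'
#' @param ccdf Tibble from [length_ccdf()], optionally with a grouping column.
#' @param colour Optional name of a grouping column for colour.
#' @export
plot_length_ccdf <- function(ccdf, colour = NULL) {
  aes <- if (is.null(colour)) {
    ggplot2::aes(x = .data$length, y = .data$ccdf)
  } else {
    ggplot2::aes(x = .data$length, y = .data$ccdf, colour = .data[[colour]])
  }
  ggplot2::ggplot(ccdf, aes) +
    ggplot2::geom_step() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "segment length L (beats)", y = "P(L ≥ l)")
}
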