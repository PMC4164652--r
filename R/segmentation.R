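#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum absolute difference between the empirical cumulative
#' distribution functions of two samples, evaluated over the pooled data
#' points.  Symmetric in its arguments; ties are handled by evaluating the
#' CDFs only at realizable points.
#'
#' @param a,b Non-empty numeric samples.
#' @return `D` in `[0, 1]`.
#' @examples
#' ks_distance(c(1, 2), c(2, 3)) # 0.5
#' @export
ks_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) abort("both samples must be non-empty")
  if (anyNA(a) || anyNA(b)) abort("samples must not contain missing values")
  ks_distance_cpp(a, b)
}

#' Locate the maximal-KS cut in a window
#'
#' Every interior beat of the window is considered as a potential cutting
#' point; the KS distance between the empirical distributions of the left
#' and right sides is computed for each, restricted so that both sides keep
#' at least `l0` beats.  Ties are broken to the smallest cut position.
#'
#' @param series A [beat_series()], data frame, or numeric vector.
#' @param start,end Half-open 0-based window `[start, end)`; defaults to the
#'   whole series.  Must satisfy `end - start >= 2 * l0`.
#' @param l0 Minimum segment length (>= 2).
#' @return A list with `cut` (absolute 0-based position `t`: left side is
#'   `[start, t)`, right side `[t, end)`) and `d_max`.
#' @export
find_max_cut <- function(series, start = 0L, end = NULL, l0 = 33L) {
  vals <- beat_values(series)
  end <- end %||% length(vals)
  if (l0 < 2L) abort("l0 must be >= 2")
  n <- end - start
  if (n < 2L * l0) {
    abort(sprintf("window of length %d is shorter than 2 * l0 = %d", n, 2L * l0))
  }
  res <- max_ks_cut_cpp(vals[(start + 1L):end], as.integer(l0))
  list(cut = start + res$cut, d_max = res$d_max)
}

#' Segment a beat series into stationarity patches
#'
#' Recursive binary splitting: the window's maximal-KS cut is applied
#' whenever `D_max` exceeds the chance level `D_crit(window length, alpha)`,
#' and the procedure recurses into both halves (depth-first, left first)
#' until no segmentable patches are left.  Windows shorter than `2 * l0`
#' are never split, so every returned patch has at least `l0` beats (except
#' a whole series shorter than `2 * l0`, returned as a single segment).
#'
#' @param series A [beat_series()], data frame, or numeric vector.
#' @param alpha Significance level; ignored when `critical_curve` is given.
#' @param l0 Minimum segment length in beats.  The default 33 corresponds to
#'   the upper edge of the very-low-frequency band of heart rate regulation
#'   (0.03 Hz, i.e. ~33 beats at a 1 Hz beat rate).
#' @param critical_curve A `ks_critical_curve`; default is the shipped
#'   Monte-Carlo table at level `alpha` (see [default_critical_curve()]).
#'   Its `l0` must match.
#' @return A tibble of class `sbp_segmentation`, one row per patch, with
#'   columns `segment`, `start`, `end` (half-open, 0-based), `length`,
#'   `mean`, `variance` (unbiased, denominator `length - 1`).
#' @examples
#' \donttest{
#' bs <- gen_piecewise_stationary(800, 400, means = c(0, 3), sds = c(1, 1), seed = 2)
#' seg <- segment_series(bs)
#' glance(seg)
#' }
#' @export
segment_series <- function(series, alpha = 0.01, l0 = 33L, critical_curve = NULL) {
  vals <- beat_values(series)
  n <- length(vals)
  if (n < 1L) abort("series must have at least one beat")
  curve <- critical_curve %||% default_critical_curve(alpha)
  if (!is.null(curve$l0) && curve$l0 != l0 && is.null(curve$fun)) {
    abort(sprintf("critical curve was calibrated for l0 = %d, not l0 = %d",
                  curve$l0, l0))
  }
  l0 <- as.integer(l0)
  cuts <- integer()
  # depth-first, left first; explicit stack to keep deep recursions cheap
  stack <- list(c(0L, n))
  while (length(stack)) {
    w <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    s <- w[1]; e <- w[2]
    if (e - s < 2L * l0) next
    res <- max_ks_cut_cpp(vals[(s + 1L):e], l0)
    if (res$d_max > d_crit(curve, e - s)) {
      t <- s + res$cut
      cuts <- c(cuts, t)
      stack[[length(stack) + 1L]] <- c(t, e)
      stack[[length(stack) + 1L]] <- c(s, t)
    }
  }
  bounds <- c(0L, sort(cuts), n)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  out <- tibble::tibble(
    segment = seq_along(starts),
    start = starts,
    end = ends,
    length = ends - starts,
    mean = vapply(seq_along(starts),
                  function(i) mean(vals[(starts[i] + 1L):ends[i]]), numeric(1)),
    variance = vapply(seq_along(starts),
                      function(i) var(vals[(starts[i] + 1L):ends[i]]), numeric(1))
  )
  # a single-beat series has no defined sample variance; report 0 spread
  out$variance[out$length == 1L] <- 0
  attr(out, "n_beats") <- n
  attr(out, "alpha") <- curve$alpha
  attr(out, "l0") <- l0
  class(out) <- c("sbp_segmentation", class(out))
  out
}

#' Per-beat local mean from a segmentation
#'
#' The step function mapping each beat to the mean of its stationarity patch
#' (the light-orange overlay of the classic segmentation portrait).
#'
#' @param segmentation An `sbp_segmentation`.
#' @return A tibble with columns `beat_index` and `local_mean`, one row per
#'   beat of the segmented series.
#' @export
local_mean_series <- function(segmentation) {
  check_segmentation(segmentation)
  tibble::tibble(
    beat_index = seq_len(sum(segmentation$length)) - 1L,
    local_mean = rep(segmentation$mean, segmentation$length)
  )
}

check_segmentation <- function(segmentation) {
  if (!is.data.frame(segmentation) ||
      !all(c("start", "end", "length", "mean", "variance") %in% names(segmentation))) {
    abort("expected a segmentation tibble with columns start, end, length, mean, variance")
  }
  invisible(segmentation)
}

#' @export
glance.sbp_segmentation <- function(x, ...) {
  tibble::tibble(
    n_beats = attr(x, "n_beats") %||% sum(x$length),
    n_segments = nrow(x),
    mean_length = mean(x$length),
    mean_variance = mean(x$variance),
    mean_mu = mean(x$mean),
    alpha = attr(x, "alpha") %||% NA_real_,
    l0 = attr(x, "l0") %||% NA_integer_
  )
}

#' @export
tidy.sbp_segmentation <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "sbp_segmentation")
  attr(out, "n_beats") <- NULL
  attr(out, "alpha") <- NULL
  attr(out, "l0") <- NULL
  out
}

#' @export
autoplot.sbp_segmentation <- function(object, series = NULL, ...) {
  lm <- local_mean_series(object)
  p <- ggplot2::ggplot()
  if (!is.null(series)) {
    vals <- beat_values(series)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(beat_index = seq_along(vals) - 1L, sbp_mmHg = vals),
      ggplot2::aes(x = .data$beat_index, y = .data$sbp_mmHg),
      linewidth = 0.2, colour = "black"
    )
  }
  p +
    ggplot2::geom_step(data = lm,
                       ggplot2::aes(x = .data$beat_index, y = .data$local_mean),
                       colour = "darkorange", linewidth = 0.8) +
    ggplot2::labs(x = "beat index", y = "SBP (mmHg)")
}

#' Read/write segmentations
#'
#' Segments CSV with columns `start`, `end`, `length`, `mean`, `variance`
#' (0-based half-open intervals).
#'
#' @param segmentation An `sbp_segmentation` tibble.
#' @param path CSV path.
#' @export
write_segments <- function(segmentation, path) {
  check_segmentation(segmentation)
  write_csv_full(tidy.sbp_segmentation(segmentation), path)
  invisible(segmentation)
}

#' @rdname write_segments
#' @export
read_segments <- function(path) {
  out <- read_csv_base(path)
  check_segmentation(out)
  attr(out, "n_beats") <- sum(out$length)
  class(out) <- c("sbp_segmentation", class(out))
  out
}
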