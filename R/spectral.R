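#' Subtract the local mean (segmentation detrending)
#'
#' Removes the patch-wise mean from the series, yielding a filtered signal
#' amenable to standard spectral analysis.  Removing the local average does
#' not guarantee stationarity (the variance may still drift), but it
#' detrends the slow baseline wanderings that dominate the raw signal.
#'
#' @param series A [beat_series()], data frame, or numeric vector.
#' @param segmentation The `sbp_segmentation` of that series.
#' @return A tibble of class `filtered_series` with columns `beat_index` and
#'   `detrended`; within-segment sums are zero to numerical tolerance.
#' @export
detrend_local_mean <- function(series, segmentation) {
  vals <- beat_values(series)
  check_segmentation(segmentation)
  if (sum(segmentation$length) != length(vals)) {
    abort(sprintf("segmentation covers %d beats but the series has %d",
                  sum(segmentation$length), length(vals)))
  }
  out <- tibble::tibble(
    beat_index = seq_along(vals) - 1L,
    detrended = vals - rep(segmentation$mean, segmentation$length)
  )
  class(out) <- c("filtered_series", class(out))
  out
}

#' Normalized sample autocorrelation
#'
#' Biased sample autocorrelation, normalized to 1 at lag 0.
#'
#' @param x Numeric vector or filtered-series tibble; must have nonzero
#'   variance.
#' @param max_lag Largest lag (beats), `< length(x)`.
#' @return Tibble with columns `lag` (0..max_lag) and `acf`.
#' @export
beat_acf <- function(x, max_lag = 200L) {
  vals <- beat_values(x)
  if (max_lag >= length(vals)) abort("max_lag must be smaller than the series length")
  if (var(vals) == 0) abort("autocorrelation undefined for zero-variance input")
  a <- acf(vals, lag.max = max_lag, plot = FALSE, demean = TRUE)
  tibble::tibble(lag = 0:max_lag, acf = as.numeric(a$acf))
}

#' Autocorrelation inside vs outside apnea epochs
#'
#' Extracts two contiguous fragments of `epoch_len` beats from the same
#' subject — the one maximizing and the one minimizing annotated-apnea
#' coverage — and returns the autocorrelation of the original and of the
#' local-mean-filtered signal in each, so the oscillation imprinted by apnea
#' can be compared against quiet sleep within-subject.
#'
#' @param series A [beat_series()] (its annotations are used unless
#'   `annotations` is supplied).
#' @param segmentation The subject's `sbp_segmentation`.
#' @param annotations Optional annotation tibble (`start_beat`, `end_beat`).
#' @param epoch_len Fragment length in beats; default 2000.
#' @param max_lag Largest lag for the autocorrelations.
#' @return A tibble with columns `epoch` (`"apnea"`/`"non_apnea"`), `signal`
#'   (`"original"`/`"filtered"`), `lag`, `acf`; fragment positions and their
#'   apnea coverage are attached as attribute `"windows"`.
#' @export
epoch_autocorr <- function(series, segmentation, annotations = NULL,
                           epoch_len = 2000L, max_lag = 200L) {
  vals <- beat_values(series)
  n <- length(vals)
  ann <- annotations %||% annotations(series)
  if (is.null(ann) || nrow(ann) == 0L) {
    abort("no apnea annotations available for this subject")
  }
  if (n < epoch_len) {
    abort(sprintf("series has %d beats, fewer than epoch_len = %d", n, epoch_len))
  }
  mask <- integer(n)
  for (i in seq_len(nrow(ann))) {
    mask[(ann$start_beat[i] + 1L):ann$end_beat[i]] <- 1L
  }
  covered <- sum(mask)
  if (covered == 0L) abort("annotations cover zero beats")
  if (covered < epoch_len && covered == n) {
    abort("no non-apnea beats available")
  }
  # windowed apnea coverage via cumulative sums: O(n)
  cs <- c(0L, cumsum(mask))
  starts <- 0:(n - epoch_len)
  cover <- cs[starts + epoch_len + 1L] - cs[starts + 1L]
  s_ap <- starts[which.max(cover)]
  s_no <- starts[which.min(cover)]
  filt <- detrend_local_mean(vals, segmentation)$detrended
  frag <- function(x, s) x[(s + 1L):(s + epoch_len)]
  res <- purrr::map_dfr(
    list(
      list(epoch = "apnea", signal = "original", x = frag(vals, s_ap)),
      list(epoch = "apnea", signal = "filtered", x = frag(filt, s_ap)),
      list(epoch = "non_apnea", signal = "original", x = frag(vals, s_no)),
      list(epoch = "non_apnea", signal = "filtered", x = frag(filt, s_no))
    ),
    function(e) dplyr::mutate(beat_acf(e$x, max_lag = max_lag),
                              epoch = e$epoch, signal = e$signal)
  )
  res <- res[c("epoch", "signal", "lag", "acf")]
  attr(res, "windows") <- tibble::tibble(
    epoch = c("apnea", "non_apnea"),
    start = c(s_ap, s_no),
    coverage = c(max(cover), min(cover)) / epoch_len
  )
  res
}

#' Welch power spectral density
#'
#' Averaged windowed periodogram of the (already detrended) beat series:
#' the signal is cut into overlapping segments, each is tapered and Fourier
#' transformed, and the one-sided power densities are averaged.  Frequencies
#' are in cycles per beat interval (beat-index domain; no conversion to Hz).
#' The normalization is density-scaled: the integral of the PSD over
#' `[0, 0.5]` estimates the signal variance.
#'
#' @param x Numeric vector or filtered-series tibble, length >= `window_len`.
#' @param window_len Taper length in beats (default 256).
#' @param overlap Fractional overlap between consecutive segments
#'   (default 0.5).
#' @param window Taper: `"hamming"` (default), `"hanning"`, or `"boxcar"`.
#' @param detrend Per-segment detrending: `"none"` (default; the pipeline
#'   feeds an already locally-demeaned signal) or `"mean"`.
#' @return A tibble of class `sbp_spectrum` with columns `frequency`
#'   (cycles/beat, `0` to `0.5`) and `power`.
#' @export
welch_psd <- function(x, window_len = 256L, overlap = 0.5,
                      window = c("hamming", "hanning", "boxcar"),
                      detrend = c("none", "mean")) {
  vals <- beat_values(x)
  window <- match.arg(window)
  detrend <- match.arg(detrend)
  n <- length(vals)
  window_len <- as.integer(window_len)
  if (n < window_len) {
    abort(sprintf("series length %d is shorter than window_len %d", n, window_len))
  }
  if (overlap < 0 || overlap >= 1) abort("overlap must be in [0, 1)")
  w <- switch(window,
    hamming = as.numeric(signal::hamming(window_len)),
    hanning = as.numeric(signal::hanning(window_len)),
    boxcar = rep(1, window_len)
  )
  step <- max(1L, as.integer(round(window_len * (1 - overlap))))
  starts <- seq.int(1L, n - window_len + 1L, by = step)
  nf <- window_len %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- vals[s:(s + window_len - 1L)]
    if (detrend == "mean") seg <- seg - mean(seg)
    X <- fft(w * seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / sum(w^2)
  }
  pxx <- acc / length(starts)
  # one-sided: fold negative frequencies into positive bins
  dbl <- 2:(nf - if (window_len %% 2L == 0L) 1L else 0L)
  pxx[dbl] <- 2 * pxx[dbl]
  out <- tibble::tibble(frequency = (seq_len(nf) - 1L) / window_len, power = pxx)
  attr(out, "window") <- window
  attr(out, "window_len") <- window_len
  attr(out, "overlap") <- overlap
  attr(out, "n_segments") <- length(starts)
  class(out) <- c("sbp_spectrum", class(out))
  out
}

#' Normalized spectral peak (A_max)
#'
#' The oscillation-strength quantifier: the maximum of the spectrum within a
#' low-frequency band, normalized by the integral of the spectrum over that
#' band (trapezoidal rule).  For a flat spectrum over a band of width `W`
#' this equals `1/W`; a dominant narrow peak drives it up.
#'
#' @param spectrum An `sbp_spectrum` (or tibble with `frequency`, `power`).
#' @param band Search/normalization band in cycles/beat, excluding DC;
#'   default `c(0.008, 0.1)`: wide enough to bracket the ~0.02 cycles/beat
#'   apneic oscillation, with the lower edge excluding the first Welch bins
#'   where local-mean detrending leaves baseline-step residue.
#' @param scale `"power"` (default) uses the PSD as the amplitude;
#'   `"amplitude"` uses its square root.
#' @return One-row tibble: `a_max`, `peak_frequency` (smallest frequency on
#'   ties), `band_lo`, `band_hi`.
#' @export
compute_amax <- function(spectrum, band = c(0.008, 0.1),
                         scale = c("power", "amplitude")) {
  scale <- match.arg(scale)
  if (length(band) != 2L || band[1] >= band[2]) abort("band must be c(lo, hi) with lo < hi")
  if (band[1] <= 0) abort("band must exclude the zero-frequency bin")
  f <- spectrum$frequency
  p <- spectrum$power
  keep <- f >= band[1] & f <= band[2]
  if (sum(keep) < 2L) abort("band contains fewer than two spectral bins")
  f <- f[keep]
  amp <- if (scale == "amplitude") sqrt(p[keep]) else p[keep]
  total <- pracma::trapz(f, amp)
  i <- which.max(amp)  # which.max returns the first (smallest frequency) tie
  tibble::tibble(a_max = amp[i] / total, peak_frequency = f[i],
                 band_lo = band[1], band_hi = band[2])
}

#' @export
autoplot.sbp_spectrum <- function(object, band = NULL, ...) {
  p <- ggplot2::ggplot(object[object$frequency > 0, ],
                       ggplot2::aes(x = .data$frequency, y = .data$power)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (cycles/beat)", y = "power density")
  if (!is.null(band)) {
    p <- p + ggplot2::annotate("rect", xmin = band[1], xmax = band[2],
                               ymin = 0, ymax = Inf, alpha = 0.15, fill = "steelblue")
  }
  p
}
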