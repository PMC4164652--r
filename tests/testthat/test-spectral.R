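test_that("local-mean detrending zeroes every patch mean", {
  # single segment: series minus its global mean
  x <- rnorm(150, mean = 120)
  never <- critical_curve_fn(function(n) 1, alpha = 0.01, l0 = 75L)
  seg <- segment_series(x, l0 = 75, critical_curve = never)
  filt <- detrend_local_mean(x, seg)
  expect_equal(filt$detrended, x - mean(x))

  # noiseless piecewise-constant series: all-zero output
  pc <- gen_piecewise_stationary(300, c(100, 200), means = c(1, 5, 2), sds = rep(0, 3))
  segpc <- segment_series(pc, l0 = 10, critical_curve = small_curve())
  expect_equal(detrend_local_mean(pc, segpc)$detrended, numeric(300))

  # random input: within-segment means vanish to numerical tolerance
  set.seed(55)
  y <- rnorm(800, mean = 100, sd = 6) + rep(c(0, 8), each = 400)
  segy <- segment_series(y, l0 = 10, critical_curve = small_curve())
  fy <- detrend_local_mean(y, segy)$detrended
  for (i in seq_len(nrow(segy))) {
    expect_lt(abs(mean(fy[(segy$start[i] + 1):segy$end[i]])), 1e-9)
  }

  expect_error(detrend_local_mean(rnorm(10), segy), "covers")
})

test_that("autocorrelation is normalized, periodic for sinusoids, flat for noise", {
  set.seed(9)
  x <- rnorm(500)
  a <- beat_acf(x, max_lag = 60)
  expect_equal(a$acf[a$lag == 0], 1)

  s <- sin(2 * pi * (0:1999) / 50)
  as <- beat_acf(s, max_lag = 100)
  expect_gte(as$acf[as$lag == 50], 0.95)

  set.seed(10)
  w <- beat_acf(rnorm(1e4), max_lag = 300)
  frac_in_band <- mean(abs(w$acf[w$lag > 0]) < 3 / sqrt(1e4))
  expect_gte(frac_in_band, 0.99)

  expect_error(beat_acf(rep(2, 100), max_lag = 10), "zero-variance")
  expect_error(beat_acf(rnorm(50), max_lag = 50), "max_lag")
})

test_that("apnea epochs carry stronger lag-period autocorrelation than quiet sleep", {
  subj <- gen_subject(subject_spec("NT", ahi = 25, n_beats = 6000,
                                   osc_amp_mmHg = 15, seed = 4))
  seg <- segment_series(subj$series, alpha = 0.01, l0 = 33)
  ea <- epoch_autocorr(subj$series, seg, epoch_len = 2000, max_lag = 80)
  expect_setequal(unique(ea$epoch), c("apnea", "non_apnea"))
  at_period <- function(ep) ea$acf[ea$epoch == ep & ea$signal == "filtered" & ea$lag == 50]
  expect_gt(at_period("apnea"), at_period("non_apnea"))
  win <- attr(ea, "windows")
  expect_gt(win$coverage[win$epoch == "apnea"], win$coverage[win$epoch == "non_apnea"])

  ctrl <- gen_subject(subject_spec("C", ahi = 0, n_beats = 4000, seed = 5))
  segc <- segment_series(ctrl$series, alpha = 0.01, l0 = 33)
  expect_error(epoch_autocorr(ctrl$series, segc), "no apnea annotations")
})

test_that("Welch PSD recovers injected peaks and preserves total power", {
  # pure sinusoid: the 0.02 cycles/beat bin dominates
  n <- 8192
  s <- 10 * sin(2 * pi * (0:(n - 1)) / 50)
  sp <- welch_psd(s, window_len = 256)
  expect_true(all(diff(sp$frequency) > 0))
  expect_true(all(sp$power >= 0))
  expect_lte(max(sp$frequency), 0.5)
  peak <- sp$frequency[which.max(sp$power)]
  expect_lte(abs(peak - 0.02), 1 / 256)

  # Parseval: band-integrated PSD of white noise matches its variance
  set.seed(77)
  wn <- rnorm(2^14, sd = 3)
  spw <- welch_psd(wn, window_len = 256)
  tot <- pracma::trapz(spw$frequency, spw$power)
  expect_lt(abs(tot - var(wn)) / var(wn), 0.10)

  # doubling the sinusoid amplitude quadruples its peak power
  sp2 <- welch_psd(2 * s, window_len = 256)
  expect_equal(max(sp2$power) / max(sp$power), 4, tolerance = 1e-9)

  expect_error(welch_psd(rnorm(100), window_len = 256), "shorter")
})

test_that("A_max is the band-normalized spectral maximum", {
  # flat spectrum over a band of width W -> a_max = 1/W
  flat <- tibble::tibble(frequency = seq(0, 0.5, by = 1 / 256), power = 2)
  band <- c(1 / 512, 0.1)
  am <- compute_amax(flat, band = band)
  f <- flat$frequency[flat$frequency >= band[1] & flat$frequency <= band[2]]
  expect_equal(am$a_max, 1 / (max(f) - min(f)))

  # an injected narrow peak strictly increases a_max
  peaked <- flat
  peaked$power[which.min(abs(peaked$frequency - 0.02))] <- 40
  expect_gt(compute_amax(peaked, band = band)$a_max, am$a_max)
  expect_equal(compute_amax(peaked, band = band)$peak_frequency,
               peaked$frequency[which.min(abs(peaked$frequency - 0.02))])

  # amplitude reading uses the square root of the power
  am_amp <- compute_amax(peaked, band = band, scale = "amplitude")
  expect_false(isTRUE(all.equal(am_amp$a_max, compute_amax(peaked, band = band)$a_max)))

  expect_error(compute_amax(flat, band = c(0, 0.1)), "zero-frequency")
  expect_error(compute_amax(flat, band = c(0.4, 0.2)), "lo < hi")
})

test_that("the filtered signal is already centred at the whole-record level", {
  set.seed(31)
  x <- rnorm(600) + rep(c(0, 6, 2), each = 200)
  seg <- segment_series(x, l0 = 10, critical_curve = small_curve())
  f1 <- detrend_local_mean(x, seg)$detrended
  # single-segment re-detrending (subtracting the global mean) is a no-op
  expect_lt(abs(mean(f1)), 1e-12)
  whole <- tibble::tibble(segment = 1L, start = 0L, end = 600L, length = 600L,
                          mean = mean(f1), variance = var(f1))
  f2 <- detrend_local_mean(f1, whole)$detrended
  expect_equal(f2, f1, tolerance = 1e-12)
})
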