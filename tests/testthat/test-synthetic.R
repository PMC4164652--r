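test_that("piecewise generator honours block means, sds and determinism", {
  # no noise, no cuts -> constant series
  bs <- gen_piecewise_stationary(1000, means = 120, sds = 0)
  expect_s3_class(bs, "beat_series")
  expect_equal(bs$sbp_mmHg, rep(120, 1000))

  # block sample means within 3 standard errors of the specification
  bs <- gen_piecewise_stationary(200, changepoints = 100, means = c(0, 5),
                                 sds = c(1, 1), seed = 7)
  se <- 1 / sqrt(100)
  expect_lt(abs(mean(bs$sbp_mmHg[1:100]) - 0), 3 * se)
  expect_lt(abs(mean(bs$sbp_mmHg[101:200]) - 5), 3 * se)

  # same call, same seed -> identical
  again <- gen_piecewise_stationary(200, changepoints = 100, means = c(0, 5),
                                    sds = c(1, 1), seed = 7)
  expect_identical(bs$sbp_mmHg, again$sbp_mmHg)
})

test_that("piecewise generator rejects malformed specifications", {
  expect_error(gen_piecewise_stationary(100, c(50, 40), means = c(0, 1, 2),
                                        sds = c(1, 1, 1)), "strictly increasing")
  expect_error(gen_piecewise_stationary(100, 50, means = c(0, 1), sds = c(1, -1)),
               "non-negative")
  expect_error(gen_piecewise_stationary(100, 150, means = c(0, 1), sds = c(1, 1)),
               "inside")
  expect_error(gen_piecewise_stationary(100, 50, means = c(0, 1, 2), sds = rep(1, 3)),
               "means")
})

test_that("apnea oscillation is epoch-gated with the requested period", {
  expect_equal(gen_apnea_oscillation(100, 50, 0,
                                     data.frame(start_beat = 0, end_beat = 50)),
               numeric(100))
  expect_equal(gen_apnea_oscillation(100, 50, 10, NULL), numeric(100))

  # dominant discrete-Fourier frequency of a gated period-50 sinusoid
  sig <- gen_apnea_oscillation(1000, 50, 10,
                               data.frame(start_beat = 0, end_beat = 500))
  expect_equal(sig[501:1000], numeric(500))
  pg <- Mod(fft(sig))^2
  freqs <- (seq_along(pg) - 1) / length(pg)
  half <- 2:(length(pg) %/% 2)
  expect_equal(freqs[half][which.max(pg[half])], 0.02)

  # phase restarts at each epoch start
  two <- gen_apnea_oscillation(300, 50, 5,
                               data.frame(start_beat = c(0, 200), end_beat = c(50, 250)))
  expect_equal(two[1:50], two[201:250])

  expect_error(
    gen_apnea_oscillation(100, 50, 1,
                          data.frame(start_beat = c(0, 30), end_beat = c(40, 80))),
    "disjoint"
  )
})

test_that("subject generator records consistent ground truth", {
  # control subjects never carry apnea epochs
  ctrl <- gen_subject(subject_spec("C", ahi = 0, n_beats = 2000, seed = 3))
  expect_equal(nrow(ctrl$true_apnea_intervals), 0L)
  expect_null(annotations(ctrl$series))

  # realized apnea fraction tracks the AHI map (capped at 0.9)
  sp <- subject_spec("HT", ahi = 60, n_beats = 21600, seed = 5)
  expect_equal(sp$apnea_fraction, min(0.9, 60 * 50 / 3600))
  subj <- gen_subject(sp)
  iv <- subj$true_apnea_intervals
  realized <- sum(iv$end_beat - iv$start_beat) / sp$n_beats
  expect_lt(abs(realized - sp$apnea_fraction), 0.05)
  # intervals disjoint, sorted, in range
  expect_true(all(diff(iv$start_beat) > 0))
  expect_true(all(iv$start_beat[-1] >= iv$end_beat[-nrow(iv)]))
  expect_true(all(iv$start_beat >= 0) && all(iv$end_beat <= sp$n_beats))
  # change points strictly inside the record
  expect_true(all(subj$true_changepoints > 0 &
                    subj$true_changepoints < sp$n_beats))

  # determinism and seed sensitivity
  expect_identical(gen_subject(sp)$series$sbp_mmHg, subj$series$sbp_mmHg)
  other <- gen_subject(subject_spec("HT", ahi = 60, n_beats = 21600, seed = 6))
  expect_false(identical(other$series$sbp_mmHg, subj$series$sbp_mmHg))
  # same generating distribution: summary statistics agree loosely
  expect_lt(abs(mean(other$series$sbp_mmHg) - mean(subj$series$sbp_mmHg)), 15)
})

test_that("cohort generator reproduces the study design", {
  ch <- gen_cohort(group_sizes = c(HT = 10L, NT = 16L, C = 7L), seed = 11,
                   n_beats = 500)
  expect_equal(nrow(ch$metadata), 33L)
  expect_equal(as.integer(table(ch$metadata$group)[c("HT", "NT", "C")]),
               c(10L, 16L, 7L))
  expect_true(all(ch$metadata$ahi[ch$metadata$group != "C"] > 15))
  expect_true(all(ch$metadata$ahi[ch$metadata$group == "C"] < 5))
  # every C subject has zero annotated apnea beats
  for (i in which(ch$metadata$group == "C")) {
    expect_equal(nrow(ch$subjects[[i]]$true_apnea_intervals), 0L)
  }
  # byte-identical regeneration under the same root seed
  again <- gen_cohort(group_sizes = c(HT = 10L, NT = 16L, C = 7L), seed = 11,
                      n_beats = 500)
  expect_identical(lapply(again$subjects, function(s) s$series$sbp_mmHg),
                   lapply(ch$subjects, function(s) s$series$sbp_mmHg))

  expect_warning(
    gen_cohort(group_sizes = c(HT = 1L, C = 1L),
               ahi_ranges = list(HT = c(5, 10), C = c(0, 5)),
               seed = 1, n_beats = 500),
    "recruitment"
  )
})
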