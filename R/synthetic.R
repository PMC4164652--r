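#' Generate a piecewise-stationary Gaussian series
#'
#' Draws independent Gaussian beats whose mean and standard deviation are
#' constant within each block delimited by the change points.  This is the
#' elementary building block of the synthetic cohort and the null/recovery
#' fixture for the segmentation procedure.
#'
#' @param n_beats Series length.
#' @param changepoints Strictly increasing integer positions inside
#'   `(0, n_beats)`; block `k` covers the half-open range
#'   `[changepoints[k-1], changepoints[k])` (0-based).
#' @param means,sds Numeric vectors of block means and standard deviations,
#'   of length `length(changepoints) + 1`; all `sds >= 0`.
#' @param seed Optional integer seed for reproducibility.
#' @return A [beat_series()] of length `n_beats`.
#' @examples
#' gen_piecewise_stationary(200, changepoints = 100, means = c(0, 5),
#'                          sds = c(1, 1), seed = 7)
#' @export
gen_piecewise_stationary <- function(n_beats, changepoints = integer(),
                                     means, sds, seed = NULL) {
  changepoints <- as.integer(changepoints)
  if (length(changepoints)) {
    if (any(changepoints <= 0L) || any(changepoints >= n_beats)) {
      abort("changepoints must lie strictly inside (0, n_beats)")
    }
    if (any(diff(changepoints) <= 0L)) abort("changepoints must be strictly increasing")
  }
  k <- length(changepoints) + 1L
  if (length(means) != k || length(sds) != k) {
    abort(sprintf("need %d means and sds for %d changepoints", k, k - 1L))
  }
  if (any(sds < 0)) abort("block standard deviations must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  len <- diff(c(0L, changepoints, n_beats))
  vals <- rnorm(n_beats, mean = rep(means, len), sd = rep(sds, len))
  beat_series(vals)
}

#' Generate an epoch-gated apnea oscillation
#'
#' Apneic episodes imprint slow, quasi-periodic swings on the blood pressure
#' signal.  This returns the additive component: a sinusoid of the given
#' period and amplitude inside each epoch interval and zero outside, with the
#' phase restarting at every epoch start (epochs are physiologically
#' independent events).
#'
#' @param n_beats Output length.
#' @param period_beats Oscillation period in beats (>= 2); the canonical
#'   apneic cycle is about 50 beats, i.e. 0.02 cycles/beat.
#' @param amp Amplitude (mmHg), >= 0.
#' @param epoch_intervals Data frame with columns `start_beat`, `end_beat`
#'   (half-open, 0-based, disjoint, in range), or `NULL`/empty for none.
#' @return Numeric vector of length `n_beats`.
#' @export
gen_apnea_oscillation <- function(n_beats, period_beats, amp, epoch_intervals = NULL) {
  if (period_beats < 2) abort("period_beats must be >= 2")
  if (amp < 0) abort("amp must be non-negative")
  out <- numeric(n_beats)
  if (amp == 0 || is.null(epoch_intervals) || NROW(epoch_intervals) == 0L) return(out)
  ep <- validate_annotations(epoch_intervals, n_beats)
  for (i in seq_len(nrow(ep))) {
    idx <- seq.int(ep$start_beat[i], ep$end_beat[i] - 1L)
    out[idx + 1L] <- amp * sin(2 * pi * (idx - ep$start_beat[i]) / period_beats)
  }
  out
}

#' Map an apnea-hypopnea index to the fraction of the night spent in apnea
#'
#' Each scored event (an airflow break of at least 10 s plus its oscillatory
#' aftermath) is modelled as occupying a fixed number of beats; at `AHI`
#' events per hour the occupied fraction is
#' `AHI * event_len_beats / beats_per_hour`, capped so that some baseline
#' always remains.
#'
#' @param ahi Events per hour (>= 0).
#' @param event_len_beats Beats occupied per event; default 50 beats
#'   (about 50 s at 60 bpm, one full cycle of the ~0.02 cycles/beat
#'   oscillation).
#' @param beats_per_hour Beats per hour at the assumed mean heart rate
#'   (default 3600, i.e. 60 bpm).
#' @param cap Upper bound on the fraction (default 0.9).
#' @return Fraction in `[0, cap]`.
#' @export
ahi_to_apnea_fraction <- function(ahi, event_len_beats = 50, beats_per_hour = 3600,
                                  cap = 0.9) {
  if (any(ahi < 0)) abort("ahi must be non-negative")
  pmin(cap, ahi * event_len_beats / beats_per_hour)
}

#' Specify one synthetic subject
#'
#' Bundles every knob of the per-subject generator.  Group-dependent defaults
#' (`NULL` arguments) encode the cohort phenomenology the pipeline is meant
#' to detect: hypertensive (HT) subjects sit at a higher pressure baseline;
#' control (C) subjects have a more active blood pressure regulation, i.e.
#' more frequent baseline shifts and hence shorter stationarity patches; and
#' apneic subjects carry epoch-gated oscillations near 0.02 cycles/beat whose
#' night coverage grows with AHI.
#'
#' @param group One of `"HT"`, `"NT"`, `"C"`.
#' @param ahi Apnea-hypopnea index, events/hour (>= 0).
#' @param n_beats Series length; default 10800 beats (a 3 h analysis window
#'   at 60 bpm; pass 21600 for a full 6 h night).
#' @param baseline_mmHg Baseline pressure level; default 155 for HT, 120
#'   otherwise.
#' @param baseline_sd_mmHg Beat-scale noise SD; default 4 mmHg.
#' @param seg_rate Expected baseline mean-shift rate, shifts per 1000 beats.
#'   Default `3 / (1 + ahi / 10)`: controls (low AHI) shift often, severe
#'   apneics rarely, which builds in the observed ordering of mean patch
#'   lengths.
#' @param shift_sd_mmHg SD of baseline jumps; default 10 mmHg.
#' @param osc_period_beats Apnea oscillation period; default 50 beats.
#' @param osc_amp_mmHg Apnea oscillation amplitude; default 10 mmHg.
#' @param apnea_fraction Fraction of beats inside apnea epochs; default
#'   derived from `ahi` via [ahi_to_apnea_fraction()]. Forced to 0 for
#'   group C.
#' @param event_len_beats Beats per scored event (see
#'   [ahi_to_apnea_fraction()]).
#' @param seed Integer RNG seed for this subject.
#' @param subject_id Optional identifier.
#' @return A list of class `subject_spec`.
#' @export
subject_spec <- function(group = c("HT", "NT", "C"), ahi, n_beats = 10800,
                         baseline_mmHg = NULL, baseline_sd_mmHg = 4,
                         seg_rate = NULL, shift_sd_mmHg = 10,
                         osc_period_beats = 50, osc_amp_mmHg = 10,
                         apnea_fraction = NULL, event_len_beats = 50,
                         seed = 1L, subject_id = NULL) {
  group <- match.arg(group)
  if (ahi < 0) abort("ahi must be non-negative")
  if (osc_period_beats < 2) abort("osc_period_beats must be >= 2")
  if (n_beats < 2L * event_len_beats) abort("n_beats too small for even one event")
  baseline_mmHg <- baseline_mmHg %||% if (group == "HT") 155 else 120
  seg_rate <- seg_rate %||% (3 / (1 + ahi / 10))
  if (group == "C") {
    apnea_fraction <- 0
  } else {
    apnea_fraction <- apnea_fraction %||% ahi_to_apnea_fraction(ahi, event_len_beats)
  }
  if (apnea_fraction < 0 || apnea_fraction > 1) abort("apnea_fraction must be in [0, 1]")
  structure(
    list(
      group = group, ahi = ahi, n_beats = as.integer(n_beats),
      baseline_mmHg = baseline_mmHg, baseline_sd_mmHg = baseline_sd_mmHg,
      seg_rate = seg_rate, shift_sd_mmHg = shift_sd_mmHg,
      osc_period_beats = osc_period_beats, osc_amp_mmHg = osc_amp_mmHg,
      apnea_fraction = apnea_fraction, event_len_beats = as.integer(event_len_beats),
      seed = as.integer(seed),
      subject_id = subject_id %||% sprintf("%s_ahi%02d_seed%d", group, round(ahi), seed)
    ),
    class = "subject_spec"
  )
}

# Disjoint apnea epochs realizing (approximately) the requested fraction:
# the night is cut into one slot per event and each event is placed uniformly
# inside its slot, so epochs never overlap and the realized coverage equals
# n_events * event_len / n_beats exactly.
place_apnea_epochs <- function(n_beats, apnea_fraction, event_len_beats) {
  n_events <- round(apnea_fraction * n_beats / event_len_beats)
  n_events <- min(n_events, floor(0.9 * n_beats / event_len_beats))
  if (n_events < 1L) {
    return(tibble::tibble(start_beat = integer(), end_beat = integer()))
  }
  bounds <- floor(n_beats / n_events * (0:n_events))
  room <- diff(bounds) - event_len_beats + 1L
  start <- as.integer(bounds[-(n_events + 1L)] + floor(runif(n_events, 0, room)))
  tibble::tibble(start_beat = start, end_beat = start + as.integer(event_len_beats))
}

# Baseline change points: Poisson count at seg_rate shifts / 1000 beats,
# positions jittered on a coarse grid so that shifts stay well separated
# (recoverable patches, min spacing ~90 beats).
place_changepoints <- function(n_beats, seg_rate) {
  n_cp <- rpois(1L, seg_rate * n_beats / 1000)
  grid <- seq(150L, n_beats - 150L, by = 150L)
  n_cp <- min(n_cp, length(grid))
  if (n_cp < 1L) return(integer())
  cp <- sort(sample(grid, n_cp)) + sample(-60L:60L, n_cp, replace = TRUE)
  as.integer(cp)
}

#' Generate one synthetic subject
#'
#' Composes a piecewise-stationary baseline (random mean shifts), an
#' epoch-gated apnea oscillation and beat-scale Gaussian noise, and records
#' the ground truth (change points and apnea intervals) for recovery tests.
#'
#' @param spec A [subject_spec()].
#' @return A list of class `synthetic_subject` with elements `series`
#'   (a [beat_series()] carrying the apnea intervals as annotations),
#'   `true_changepoints`, `true_apnea_intervals`, and `spec`.
#' @export
gen_subject <- function(spec) {
  stopifnot(inherits(spec, "subject_spec"))
  set.seed(spec$seed)
  cp <- place_changepoints(spec$n_beats, spec$seg_rate)
  shifts <- rnorm(length(cp), 0, spec$shift_sd_mmHg)
  means <- spec$baseline_mmHg + cumsum(c(0, shifts))
  epochs <- place_apnea_epochs(spec$n_beats, spec$apnea_fraction, spec$event_len_beats)
  baseline <- rep(means, diff(c(0L, cp, spec$n_beats)))
  osc <- gen_apnea_oscillation(spec$n_beats, spec$osc_period_beats,
                               spec$osc_amp_mmHg, epochs)
  noise <- rnorm(spec$n_beats, 0, spec$baseline_sd_mmHg)
  ann <- if (nrow(epochs)) dplyr::mutate(epochs, label = "apnea") else NULL
  structure(
    list(
      series = beat_series(baseline + osc + noise, annotations = ann),
      true_changepoints = cp,
      true_apnea_intervals = epochs,
      spec = spec
    ),
    class = "synthetic_subject"
  )
}

#' Generate a synthetic cohort
#'
#' Mirrors the reference study design: apneic hypertensive (HT) and
#' normotensive (NT) groups recruited with AHI above 15, plus a non-apneic
#' control group (C) with AHI below 5.  Per-subject AHIs are drawn uniformly
#' from the group range and per-subject seeds are derived deterministically
#' from the root seed (`seed + 7919 * subject_number`), so the cohort is
#' reproducible subject by subject.
#'
#' @param group_sizes Named integer vector; default `c(HT = 10, NT = 16, C = 7)`.
#' @param ahi_ranges Named list of `c(lo, hi)` AHI ranges per group; defaults
#'   `HT = c(20, 50)`, `NT = c(15, 30)`, `C = c(0, 5)`. An apneic range
#'   dipping below 15 triggers a warning (recruitment rule).
#' @param osc_amp_range Per-subject apnea oscillation amplitudes are drawn
#'   uniformly from this range (mmHg); real cohorts show wide inter-subject
#'   variability in how strongly events imprint on blood pressure.
#' @param seed Root seed.
#' @param ... Further arguments passed to [subject_spec()] (e.g. `n_beats`).
#' @return A list of class `synthetic_cohort` with elements `subjects` (list
#'   of [gen_subject()] results) and `metadata` (tibble: `subject_id`,
#'   `group`, `ahi`, `seed`).
#' @export
gen_cohort <- function(group_sizes = c(HT = 10L, NT = 16L, C = 7L),
                       ahi_ranges = list(HT = c(20, 50), NT = c(15, 30), C = c(0, 5)),
                       osc_amp_range = c(1, 14), seed = 1L, ...) {
  if (any(group_sizes < 1L)) abort("group sizes must be >= 1")
  groups <- names(group_sizes)
  if (is.null(groups) || !all(groups %in% c("HT", "NT", "C"))) {
    abort("group_sizes must be named with labels among HT, NT, C")
  }
  for (g in setdiff(groups, "C")) {
    rng <- ahi_ranges[[g]]
    if (any(rng < 0)) abort("AHI ranges must be non-negative")
    if (min(rng) < 15) {
      warn(sprintf("group %s AHI range dips below the AHI > 15 recruitment rule", g))
    }
  }
  set.seed(seed)
  ahis <- unlist(lapply(groups, function(g) {
    rng <- ahi_ranges[[g]]
    runif(group_sizes[[g]], rng[1], rng[2])
  }))
  amps <- runif(length(ahis), osc_amp_range[1], osc_amp_range[2])
  group_vec <- rep(groups, group_sizes)
  subjects <- vector("list", length(ahis))
  meta <- vector("list", length(ahis))
  for (i in seq_along(ahis)) {
    child_seed <- as.integer((seed + 7919 * i) %% .Machine$integer.max)
    id <- sprintf("%s%02d", group_vec[i], i)
    sp <- subject_spec(group = group_vec[i], ahi = ahis[i],
                       osc_amp_mmHg = amps[i], seed = child_seed,
                       subject_id = id, ...)
    subjects[[i]] <- gen_subject(sp)
    meta[[i]] <- tibble::tibble(subject_id = id, group = group_vec[i],
                                ahi = ahis[i], osc_amp_mmHg = amps[i],
                                seed = child_seed)
  }
  structure(
    list(subjects = subjects, metadata = dplyr::bind_rows(meta), seed = seed),
    class = "synthetic_cohort"
  )
}

#' Write a synthetic cohort to disk
#'
#' One series CSV and (where present) one annotation CSV per subject, a
#' cohort metadata CSV, and a JSON sidecar with the generator ground truth.
#'
#' @param cohort A [gen_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- list()
  for (s in cohort$subjects) {
    id <- s$spec$subject_id
    write_beat_series(s$series, file.path(dir, paste0(id, ".csv")))
    truth[[id]] <- list(
      changepoints = s$true_changepoints,
      apnea_intervals = s$true_apnea_intervals,
      ahi = s$spec$ahi, group = s$spec$group, seed = s$spec$seed
    )
  }
  write_csv_full(cohort$metadata, file.path(dir, "metadata.csv"))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
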