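#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default.
#'
#' @param alpha Segmentation significance level.
#' @param l0 Minimum segment length (beats).
#' @param critical_curve Optional `ks_critical_curve`; default the shipped
#'   table at `alpha`.
#' @param window_len,overlap,window Welch estimator parameters.
#' @param band A_max search/normalization band (cycles/beat).
#' @param amax_scale `"power"` or `"amplitude"` (see [compute_amax()]).
#' @param weighted Beat-weighted per-subject means (see [subject_features()]).
#' @param combine 2-D rule variant (see [rule2d_evaluate()]).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.01, l0 = 33L, critical_curve = NULL,
                            window_len = 256L, overlap = 0.5,
                            window = "hamming", band = c(0.008, 0.1),
                            amax_scale = "power", weighted = FALSE,
                            combine = "and") {
  structure(
    list(alpha = alpha, l0 = as.integer(l0), critical_curve = critical_curve,
         window_len = as.integer(window_len), overlap = overlap,
         window = window, band = band, amax_scale = amax_scale,
         weighted = weighted, combine = combine),
    class = "pipeline_config"
  )
}

# Segmentation + detrending + spectrum + features for one subject.
analyse_subject <- function(series, config, subject_id = NA_character_,
                            group = NA_character_, ahi = NA_real_) {
  seg <- segment_series(series, alpha = config$alpha, l0 = config$l0,
                        critical_curve = config$critical_curve)
  filt <- detrend_local_mean(series, seg)
  spec <- if (n_beats(series) >= config$window_len) {
    welch_psd(filt, window_len = config$window_len, overlap = config$overlap,
              window = config$window)
  } else {
    NULL
  }
  amax <- if (is.null(spec)) {
    tibble::tibble(a_max = NA_real_, peak_frequency = NA_real_)
  } else {
    compute_amax(spec, band = config$band, scale = config$amax_scale)
  }
  list(
    segmentation = seg,
    spectrum = spec,
    features = subject_features(seg, a_max = amax$a_max,
                                subject_id = subject_id, group = group,
                                ahi = ahi, weighted = config$weighted)
  )
}

#' Run the full analysis pipeline on a cohort
#'
#' Per subject: KS segmentation, patch quantifiers, local-mean detrending,
#' Welch spectrum and `A_max`.  Cohort level: pooled segment-length CCDFs,
#' two-sample KS group comparisons, Pearson correlations of each feature with
#' AHI, a ROC analysis per feature, and the combined 2-D decision rule.
#' Subjects whose analysis fails are dropped with a warning and the cohort
#' stages run on the survivors; classification stages are skipped (with a
#' warning) unless both apneic and control subjects survive.
#'
#' @param cohort A [gen_cohort()] result, or a directory written by
#'   [write_cohort()] (per-subject series CSVs plus `metadata.csv`).
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, features/CCDF/ROC CSVs and
#'   a JSON report are written there.
#' @return A list of class `sbp_report`: `features`, `segmentations`,
#'   `ccdf`, `ks_tests`, `correlations`, `roc` (named list of `sbp_roc`),
#'   `rule2d`, `config`, `failed`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  if (is.character(cohort)) cohort <- read_cohort_dir(cohort)
  stopifnot(inherits(cohort, "synthetic_cohort") || is.list(cohort))
  config$critical_curve <- config$critical_curve %||% default_critical_curve(config$alpha)
  meta <- cohort$metadata
  subjects <- cohort$subjects
  feats <- list(); segs <- list(); lens <- list(); failed <- character()
  for (i in seq_along(subjects)) {
    id <- meta$subject_id[i]
    res <- tryCatch(
      analyse_subject(subjects[[i]]$series, config, subject_id = id,
                      group = meta$group[i], ahi = meta$ahi[i]),
      error = function(e) {
        warn(sprintf("subject %s failed and was dropped: %s", id, conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) { failed <- c(failed, id); next }
    feats[[id]] <- res$features
    segs[[id]] <- res$segmentation
    lens[[id]] <- dplyr::mutate(length_ccdf(res$segmentation),
                                subject_id = id, group = meta$group[i])
  }
  if (!length(feats)) abort("every subject failed; nothing to report")
  features <- dplyr::bind_rows(feats)
  features$apneic <- is_apneic(features$group)
  pooled <- purrr::map_dfr(unique(features$group), function(g) {
    ids <- features$subject_id[features$group == g]
    all_len <- unlist(lapply(segs[ids], function(s) s$length), use.names = FALSE)
    dplyr::mutate(length_ccdf(all_len), group = g)
  })
  ks_tests <- dplyr::bind_rows(
    group_ks_tests(features, "mean_L"),
    group_ks_tests(features, "mean_var"),
    group_ks_tests(features, "mean_mu"),
    if (!anyNA(features$a_max)) group_ks_tests(features, "a_max")
  )
  correlations <- purrr::map_dfr(c("mean_L", "mean_var", "mean_mu", "a_max"), function(f) {
    v <- features[[f]]
    ok <- is.finite(v)
    r <- if (sum(ok) >= 3 && sd(v[ok]) > 0) pearson_r(v[ok], features$ahi[ok]) else NA_real_
    tibble::tibble(feature = f, pearson_r = r, n = sum(ok))
  })
  both_classes <- length(unique(features$apneic)) == 2L
  roc <- NULL; rule2d <- NULL
  if (both_classes) {
    roc <- list(
      mean_L = roc_curve(features, "mean_L", "apneic"),
      mean_var = roc_curve(features, "mean_var", "apneic")
    )
    if (!anyNA(features$a_max)) {
      roc$a_max <- roc_curve(features, "a_max", "apneic")
      rule2d <- rule2d_evaluate(features, combine = config$combine)
    }
  } else {
    warn("only one class present; classification stages skipped")
  }
  report <- structure(
    list(features = features, segmentations = segs, ccdf = pooled,
         ks_tests = ks_tests, correlations = correlations, roc = roc,
         rule2d = rule2d, config = config, failed = failed,
         seed = cohort$seed %||% NA_integer_),
    class = "sbp_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

read_cohort_dir <- function(dir) {
  meta <- read_csv_base(file.path(dir, "metadata.csv"))
  subjects <- lapply(meta$subject_id, function(id) {
    list(series = read_beat_series(file.path(dir, paste0(id, ".csv"))))
  })
  structure(list(subjects = subjects, metadata = meta, seed = NA_integer_),
            class = "synthetic_cohort")
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_full(report$features, file.path(out_dir, "features.csv"))
  write_csv_full(report$ccdf, file.path(out_dir, "ccdf.csv"))
  for (id in names(report$segmentations)) {
    write_segments(report$segmentations[[id]],
                   file.path(out_dir, paste0("segments_", id, ".csv")))
  }
  js <- list(
    ks_tests = report$ks_tests,
    correlations = report$correlations,
    failed_subjects = report$failed,
    seed = report$seed,
    config = report$config[c("alpha", "l0", "window_len", "overlap", "window",
                             "band", "amax_scale", "weighted", "combine")]
  )
  if (!is.null(report$roc)) {
    js$roc <- lapply(report$roc, function(r) as.list(glance(r)))
    for (f in names(report$roc)) {
      readr::write_csv(tidy(report$roc[[f]]),
                       file.path(out_dir, paste0("roc_", f, ".csv")))
    }
  }
  if (!is.null(report$rule2d)) js$rule2d <- as.list(glance(report$rule2d))
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' @export
print.sbp_report <- function(x, ...) {
  cat(sprintf("<sbp_report> %d subjects (%d failed)\n",
              nrow(x$features), length(x$failed)))
  cat("\nFeature ~ AHI correlations:\n")
  print(x$correlations)
  if (!is.null(x$roc)) {
    cat("\nROC summaries:\n")
    print(dplyr::bind_rows(lapply(x$roc, glance), .id = "feature"))
  }
  if (!is.null(x$rule2d)) {
    cat("\nCombined 2-D rule:\n")
    print(glance(x$rule2d))
  }
  invisible(x)
}

#' @export
glance.sbp_report <- function(x, ...) {
  out <- tibble::tibble(
    n_subjects = nrow(x$features),
    n_failed = length(x$failed),
    r_mean_L_ahi = x$correlations$pearson_r[x$correlations$feature == "mean_L"],
    r_a_max_ahi = x$correlations$pearson_r[x$correlations$feature == "a_max"]
  )
  if (!is.null(x$roc)) {
    for (f in names(x$roc)) {
      out[[paste0("acc_", f)]] <- glance(x$roc[[f]])$accuracy
    }
  }
  if (!is.null(x$rule2d)) out$acc_rule2d <- glance(x$rule2d)$accuracy
  out
}
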