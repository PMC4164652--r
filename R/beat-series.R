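#' Construct a beat-to-beat pressure series
#'
#' A beat series is the pipeline's raw input: one systolic blood pressure
#' value per heartbeat, indexed by beat number.  It is stored as a tibble
#' with columns `beat_index` (0-based, contiguous integers) and `sbp_mmHg`,
#' optionally carrying event annotations (half-open beat intervals) as an
#' attribute.
#'
#' @param values Numeric vector of per-beat pressures (mmHg); no missing
#'   values are allowed (gaps must be handled upstream).
#' @param annotations Optional data frame of labelled half-open beat
#'   intervals with columns `start_beat`, `end_beat` and optionally `label`.
#' @return A tibble of class `beat_series` with columns `beat_index` and
#'   `sbp_mmHg`.
#' @examples
#' bs <- beat_series(rnorm(100, mean = 120, sd = 4))
#' n_beats(bs)
#' @export
beat_series <- function(values, annotations = NULL) {
  values <- as.numeric(values)
  if (length(values) < 1L) abort("a beat series needs at least one value")
  if (anyNA(values)) {
    abort(sprintf(
      "beat series contains missing values at beat index(es) %s",
      paste(head(which(is.na(values)) - 1L, 5L), collapse = ", ")
    ))
  }
  out <- tibble::tibble(beat_index = seq_along(values) - 1L, sbp_mmHg = values)
  attr(out, "annotations") <- validate_annotations(annotations, length(values))
  class(out) <- c("beat_series", class(out))
  out
}

validate_annotations <- function(ann, n) {
  if (is.null(ann) || nrow(ann) == 0L) return(NULL)
  ann <- tibble::as_tibble(ann)
  if (!all(c("start_beat", "end_beat") %in% names(ann))) {
    abort("annotations need columns start_beat and end_beat")
  }
  if (!("label" %in% names(ann))) ann$label <- "apnea"
  ann <- dplyr::arrange(ann, .data$start_beat)
  if (any(ann$end_beat <= ann$start_beat)) abort("annotation intervals must have end_beat > start_beat")
  if (any(ann$start_beat < 0L) || any(ann$end_beat > n)) {
    abort("annotation intervals must lie within [0, n_beats)")
  }
  if (nrow(ann) > 1L && any(ann$start_beat[-1L] < ann$end_beat[-nrow(ann)])) {
    abort("annotation intervals must be disjoint")
  }
  ann[c("start_beat", "end_beat", "label")]
}

#' @rdname beat_series
#' @param x A `beat_series` (or any data frame with an `sbp_mmHg` column).
#' @export
n_beats <- function(x) length(beat_values(x))

#' @rdname beat_series
#' @export
annotations <- function(x) attr(x, "annotations")

# Accept a beat_series tibble, a two-column data frame, or a bare numeric
# vector wherever a signal is expected.
beat_values <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is.data.frame(x)) {
    col <- intersect(c("sbp_mmHg", "value", "detrended"), names(x))
    if (length(col) >= 1L) return(as.numeric(x[[col[1L]]]))
  }
  abort("expected a numeric vector or a data frame with an sbp_mmHg/value column")
}

# CSV reader via base R: strtod parsing is correctly rounded, so values
# written by write_csv_full() round-trip bit-exactly.
read_csv_base <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

# CSV writer with full double precision (17 significant digits), so that
# write/read round-trips reproduce the numbers bit-exactly.
write_csv_full <- function(df, path) {
  is_dbl <- vapply(df, is.double, logical(1))
  df[is_dbl] <- lapply(df[is_dbl], function(x) sprintf("%.17g", x))
  readr::write_csv(df, path)
}

#' Read and write beat series files
#'
#' Beat series are exchanged as plain CSV with header columns `beat_index`
#' (contiguous integers starting at 0) and `sbp_mmHg`; annotations travel in
#' a companion CSV with columns `start_beat`, `end_beat`, `label` (half-open,
#' 0-based intervals).
#'
#' @param path Path to the series CSV.
#' @param annotations_path Optional path to an annotation CSV. For
#'   `read_beat_series`, when `NULL` a sidecar named `<path>.annotations.csv`
#'   is picked up if present.
#' @return `read_beat_series` returns a [beat_series()]; the writers return
#'   their input invisibly.
#' @export
read_beat_series <- function(path, annotations_path = NULL) {
  df <- read_csv_base(path)
  if (!all(c("beat_index", "sbp_mmHg") %in% names(df))) {
    abort(sprintf("%s: expected columns beat_index and sbp_mmHg", path))
  }
  if (anyNA(df$sbp_mmHg) || anyNA(df$beat_index)) {
    bad <- which(is.na(df$sbp_mmHg) | is.na(df$beat_index)) + 1L
    abort(sprintf("%s: missing/non-numeric entries at line(s) %s",
                  path, paste(head(bad, 5L), collapse = ", ")))
  }
  expected <- seq_len(nrow(df)) - 1L
  if (!identical(as.integer(df$beat_index), expected)) {
    bad <- which(as.integer(df$beat_index) != expected)[1L]
    abort(sprintf(
      "%s: beat_index must be contiguous from 0; first gap at line %d (found %s, expected %d)",
      path, bad + 1L, df$beat_index[bad], expected[bad]
    ))
  }
  ann <- NULL
  if (is.null(annotations_path)) {
    side <- paste0(sub("\\.csv$", "", path), ".annotations.csv")
    if (file.exists(side)) annotations_path <- side
  }
  if (!is.null(annotations_path)) {
    ann <- read_csv_base(annotations_path)
  }
  beat_series(df$sbp_mmHg, annotations = ann)
}

#' @rdname read_beat_series
#' @param x A [beat_series()].
#' @export
write_beat_series <- function(x, path, annotations_path = NULL) {
  vals <- beat_values(x)
  write_csv_full(
    tibble::tibble(beat_index = seq_along(vals) - 1L, sbp_mmHg = vals),
    path
  )
  ann <- annotations(x)
  if (!is.null(ann)) {
    if (is.null(annotations_path)) {
      annotations_path <- paste0(sub("\\.csv$", "", path), ".annotations.csv")
    }
    readr::write_csv(ann, annotations_path)
  }
  invisible(x)
}

#' @export
autoplot.beat_series <- function(object, segmentation = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$beat_index, y = .data$sbp_mmHg))
  ann <- annotations(object)
  if (!is.null(ann)) {
    p <- p + ggplot2::geom_rect(
      data = ann, inherit.aes = FALSE,
      ggplot2::aes(xmin = .data$start_beat, xmax = .data$end_beat,
                   ymin = -Inf, ymax = Inf),
      fill = "grey80", alpha = 0.6
    )
  }
  p <- p + ggplot2::geom_line(linewidth = 0.2)
  if (!is.null(segmentation)) {
    p <- p + ggplot2::geom_segment(
      data = segmentation, inherit.aes = FALSE,
      ggplot2::aes(x = .data$start, xend = .data$end - 1L,
                   y = .data$mean, yend = .data$mean),
      colour = "darkorange", linewidth = 0.8
    )
  }
  p + ggplot2::labs(x = "beat index", y = "SBP (mmHg)")
}
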