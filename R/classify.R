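#' ROC analysis of one screening feature
#'
#' Sweeps every threshold midway between consecutive distinct feature values
#' (plus sentinels below and above the data range) under the decision rule
#' "apneic if value > threshold" (all three quantifiers rise with apnea
#' severity; set `direction = "less"` to flip), and records the true- and
#' false-positive rates at each.
#'
#' @param data Feature tibble, one row per subject.
#' @param feature Column with the feature values (unquoted or string).
#' @param label Column with the class labels (unquoted or string); logical,
#'   or coerced via `positive`.
#' @param positive Value of `label` marking the positive (apneic) class when
#'   `label` is not logical.  A `group` column's `"HT"`/`"NT"` vs `"C"`
#'   labelling can be pre-mapped with [is_apneic()].
#' @param direction `"greater"` (default): larger values indicate apnea.
#' @return A tibble of class `sbp_roc` with columns `threshold`, `fpr`,
#'   `tpr`; AUC, the corner-optimal operating point, and the confusion
#'   counts at that point are attached as attributes and summarized by
#'   [glance()].
#' @examples
#' df <- tibble::tibble(v = c(1, 2, 3, 10, 11, 12),
#'                      apneic = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
#' glance(roc_curve(df, v, apneic))
#' @export
roc_curve <- function(data, feature, label, positive = TRUE,
                      direction = c("greater", "less")) {
  direction <- match.arg(direction)
  values <- dplyr::pull(data, {{ feature }})
  labels <- dplyr::pull(data, {{ label }})
  if (!is.logical(labels)) labels <- labels == positive
  keep <- is.finite(values) & !is.na(labels)
  if (!all(keep)) {
    warn(sprintf("dropping %d subject(s) with missing feature or label", sum(!keep)))
    values <- values[keep]; labels <- labels[keep]
  }
  if (direction == "less") values <- -values
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) abort("both classes must be present")
  sv <- sort(unique(values))
  gap <- if (length(sv) > 1L) median(diff(sv)) else 1
  thresholds <- c(sv[1] - gap, (head(sv, -1) + tail(sv, -1)) / 2, sv[length(sv)] + gap)
  tpr <- vapply(thresholds, function(th) sum(values > th & labels) / n_pos, numeric(1))
  fpr <- vapply(thresholds, function(th) sum(values > th & !labels) / n_neg, numeric(1))
  out <- tibble::tibble(threshold = thresholds, fpr = fpr, tpr = tpr)
  # trapezoid over the step curve; with midpoint thresholds this equals the
  # Mann-Whitney statistic U / (n1 * n0), ties counted half
  ord <- order(fpr, tpr)
  auc <- pracma::trapz(c(0, fpr[ord], 1), c(0, tpr[ord], 1))
  attr(out, "auc") <- auc
  attr(out, "n_pos") <- n_pos
  attr(out, "n_neg") <- n_neg
  attr(out, "direction") <- direction
  opt <- optimal_threshold(out)
  attr(out, "optimal") <- opt
  attr(out, "at_optimum") <- confusion_stats(values, labels, opt)
  class(out) <- c("sbp_roc", class(out))
  out
}

#' Corner-distance optimal threshold
#'
#' The operating point closest (Euclidean) to the perfect classifier at
#' `(FPR = 0, TPR = 1)`; at equal distance the point with the lower FPR wins
#' (screening favours specificity), and at fully tied operating points the
#' larger threshold.
#'
#' @param roc An `sbp_roc` from [roc_curve()].
#' @return The optimal threshold (an element of the sweep).
#' @export
optimal_threshold <- function(roc) {
  d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  cand <- which(d <= min(d) + 1e-12)
  cand <- cand[roc$fpr[cand] <= min(roc$fpr[cand]) + 1e-12]
  roc$threshold[cand[which.max(roc$threshold[cand])]]
}

#' Confusion counts and rates at a threshold
#'
#' Decision rule: predict apneic when `value > threshold`.  Accuracy is the
#' sum of true positives and true negatives over the total sample size.
#'
#' @param values Feature values.
#' @param labels Logical (TRUE = apneic) or coercible via `positive`.
#' @param threshold Decision threshold.
#' @param positive Positive-class value when `labels` is not logical.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`, `tp`,
#'   `tn`, `fp`, `fn`, `threshold`.
#' @export
confusion_stats <- function(values, labels, threshold, positive = TRUE) {
  if (!is.logical(labels)) labels <- labels == positive
  pred <- values > threshold
  tp <- sum(pred & labels); fp <- sum(pred & !labels)
  tn <- sum(!pred & !labels); fn <- sum(!pred & labels)
  tibble::tibble(
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    tp = tp, tn = tn, fp = fp, fn = fn,
    threshold = threshold
  )
}

#' Combined two-feature decision rule
#'
#' The mean patch length and the normalized spectral peak separate apneic
#' subjects best when combined: a subject is called non-apneic only in the
#' low-`mean_L`, low-`a_max` region (both coordinates at or below their
#' thresholds), and apneic otherwise.  `combine = "or"` selects the variant
#' where exceeding both thresholds is required for an apneic call.
#'
#' @param features Feature tibble with columns `mean_L`, `a_max`, and a
#'   logical `apneic` column (or `group`, from which `apneic` is derived via
#'   [is_apneic()]).
#' @param threshold_L,threshold_A Thresholds for `mean_L` and `a_max`; by
#'   default the corner-optimal 1-D ROC thresholds computed on `features`.
#' @param combine `"and"` (default): non-apneic iff below both thresholds.
#' @param optimize When `TRUE`, ignore the default per-feature ROC thresholds
#'   and pick the pair maximizing apparent accuracy over both sweep grids
#'   (ties broken toward higher specificity, then larger thresholds).  The
#'   optimized rule's apparent accuracy can never fall below either 1-D
#'   accuracy, since switching one feature off (threshold above its range)
#'   is itself a candidate.
#' @return A tibble of class `sbp_rule2d`: the input rows plus `predicted`
#'   (logical, TRUE = apneic); thresholds and confusion stats are attached
#'   and summarized by [glance()].
#' @export
rule2d_evaluate <- function(features, threshold_L = NULL, threshold_A = NULL,
                            combine = c("and", "or"), optimize = FALSE) {
  combine <- match.arg(combine)
  if (!("apneic" %in% names(features))) {
    if (!("group" %in% names(features))) abort("features need an apneic or group column")
    features$apneic <- is_apneic(features$group)
  }
  miss <- !is.finite(features$mean_L) | !is.finite(features$a_max)
  if (any(miss)) {
    warn(sprintf("skipping %d subject(s) with a missing feature: %s", sum(miss),
                 paste(features$subject_id[miss], collapse = ", ")))
    features <- features[!miss, ]
  }
  if (optimize) {
    grid_L <- roc_curve(features, "mean_L", "apneic")$threshold
    grid_A <- roc_curve(features, "a_max", "apneic")$threshold
    best <- NULL
    for (tl in grid_L) for (ta in grid_A) {
      low <- features$mean_L <= tl & features$a_max <= ta
      pred <- if (combine == "and") !low else features$mean_L > tl & features$a_max > ta
      acc <- mean(pred == features$apneic)
      spec <- sum(!pred & !features$apneic) / sum(!features$apneic)
      cand <- c(acc, spec, tl, ta)
      if (is.null(best) ||
          acc > best[1] + 1e-12 ||
          (abs(acc - best[1]) <= 1e-12 && spec > best[2] + 1e-12) ||
          (abs(acc - best[1]) <= 1e-12 && abs(spec - best[2]) <= 1e-12 &&
             (tl > best[3] || (tl == best[3] && ta > best[4])))) {
        best <- cand
      }
    }
    threshold_L <- best[3]
    threshold_A <- best[4]
  }
  threshold_L <- threshold_L %||%
    optimal_threshold(roc_curve(features, "mean_L", "apneic"))
  threshold_A <- threshold_A %||%
    optimal_threshold(roc_curve(features, "a_max", "apneic"))
  low_low <- features$mean_L <= threshold_L & features$a_max <= threshold_A
  features$predicted <- if (combine == "and") {
    !low_low
  } else {
    features$mean_L > threshold_L & features$a_max > threshold_A
  }
  tp <- sum(features$predicted & features$apneic)
  tn <- sum(!features$predicted & !features$apneic)
  stats <- tibble::tibble(
    accuracy = (tp + tn) / nrow(features),
    sensitivity = tp / sum(features$apneic),
    specificity = tn / sum(!features$apneic),
    threshold_L = threshold_L, threshold_A = threshold_A, combine = combine
  )
  attr(features, "stats") <- stats
  class(features) <- c("sbp_rule2d", class(features))
  features
}

#' Map group labels to apnea status
#'
#' @param group Character vector of group labels; `"C"` is non-apneic,
#'   everything else apneic.
#' @return Logical vector.
#' @export
is_apneic <- function(group) group != "C"

#' @export
glance.sbp_roc <- function(x, ...) {
  opt <- attr(x, "at_optimum")
  tibble::tibble(
    auc = attr(x, "auc"),
    optimal_threshold = opt$threshold,
    accuracy = opt$accuracy,
    sensitivity = opt$sensitivity,
    specificity = opt$specificity,
    n_pos = attr(x, "n_pos"),
    n_neg = attr(x, "n_neg")
  )
}

#' @export
tidy.sbp_roc <- function(x, ...) {
  out <- x
  for (a in c("auc", "n_pos", "n_neg", "direction", "optimal", "at_optimum")) {
    attr(out, a) <- NULL
  }
  class(out) <- setdiff(class(out), "sbp_roc")
  out
}

#' @export
glance.sbp_rule2d <- function(x, ...) attr(x, "stats")

#' @export
autoplot.sbp_roc <- function(object, ...) {
  opt <- attr(object, "at_optimum")
  ggplot2::ggplot(object[order(object$fpr, object$tpr), ],
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3, colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = 1 - opt$specificity, y = opt$sensitivity,
                      colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}

#' Scatter of the two combined features with decision thresholds
#'
#' @param rule2d An `sbp_rule2d` from [rule2d_evaluate()].
#' @export
plot_features_2d <- function(rule2d) {
  st <- attr(rule2d, "stats")
  ggplot2::ggplot(rule2d, ggplot2::aes(x = .data$mean_L, y = .data$a_max,
                                       colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = st$threshold_L, linetype = 2) +
    ggplot2::geom_hline(yintercept = st$threshold_A, linetype = 2) +
    ggplot2::labs(x = "mean segment length (beats)", y = "A_max")
}
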