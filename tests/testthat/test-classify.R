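test_that("perfectly separated classes yield AUC 1 and a mid-gap threshold", {
  df <- tibble::tibble(v = c(1, 2, 3, 10, 11, 12),
                       apneic = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  roc <- roc_curve(df, v, apneic)
  g <- glance(roc)
  expect_equal(g$auc, 1)
  expect_equal(g$accuracy, 1)
  expect_equal(g$optimal_threshold, 6.5) # midpoint of the separating gap
  expect_equal(g$sensitivity, 1)
  expect_equal(g$specificity, 1)
})

test_that("AUC equals the Mann-Whitney rank statistic", {
  set.seed(19)
  for (r in 1:25) {
    n1 <- sample(5:20, 1); n0 <- sample(5:20, 1)
    v <- c(rnorm(n1, mean = runif(1, 0, 2)), rnorm(n0))
    if (r %% 4 == 0) v <- round(v) # ties across classes
    lab <- rep(c(TRUE, FALSE), c(n1, n0))
    df <- tibble::tibble(v = v, apneic = lab)
    expect_equal(attr(roc_curve(df, v, apneic), "auc"), oracle_auc_mw(v, lab),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone feature transforms", {
  set.seed(23)
  v <- c(rnorm(12, 1), rnorm(9))
  lab <- rep(c(TRUE, FALSE), c(12, 9))
  df <- tibble::tibble(v = v, w = exp(v), apneic = lab)
  expect_equal(attr(roc_curve(df, w, apneic), "auc"),
               attr(roc_curve(df, v, apneic), "auc"), tolerance = 1e-12)
})

test_that("labels shuffled at random give chance-level AUC", {
  set.seed(37)
  v <- rnorm(30)
  lab <- rep(c(TRUE, FALSE), c(15, 15))
  aucs <- vapply(1:500, function(i) {
    df <- tibble::tibble(v = v, apneic = sample(lab))
    attr(roc_curve(df, v, apneic), "auc")
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-3)
})

test_that("optimal threshold minimizes the corner distance (brute force)", {
  set.seed(41)
  for (r in 1:25) {
    v <- c(rnorm(10, runif(1, 0, 2)), rnorm(8))
    df <- tibble::tibble(v = v, apneic = rep(c(TRUE, FALSE), c(10, 8)))
    roc <- roc_curve(df, v, apneic)
    th <- optimal_threshold(roc)
    expect_true(th %in% roc$threshold)
    d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
    expect_equal(sqrt(roc$fpr[roc$threshold == th]^2 +
                        (1 - roc$tpr[roc$threshold == th])^2), min(d),
                 tolerance = 1e-12)
    # tie-break: no equally-distant point has lower FPR
    tied <- which(d <= min(d) + 1e-12)
    expect_equal(roc$fpr[roc$threshold == th], min(roc$fpr[tied]))
  }

  # an interior point beats both corners when closer to (0, 1)
  fake <- tibble::tibble(threshold = c(10, 5, 0), fpr = c(0, 0.2, 1),
                         tpr = c(0, 0.9, 1))
  expect_equal(optimal_threshold(fake), 5)
})

test_that("confusion stats implement the counting definitions", {
  v <- c(1, 2, 3, 10, 11)
  lab <- c(FALSE, FALSE, FALSE, TRUE, TRUE)
  cs <- confusion_stats(v, lab, 5)
  expect_equal(cs$accuracy, 1)
  expect_equal(c(cs$tp, cs$tn, cs$fp, cs$fn), c(2, 3, 0, 0))

  # threshold below all values on a 26 apneic / 7 control cohort:
  # everyone called apneic
  v2 <- rnorm(33)
  lab2 <- rep(c(TRUE, FALSE), c(26, 7))
  cs2 <- confusion_stats(v2, lab2, min(v2) - 1)
  expect_equal(cs2$accuracy, 26 / 33)
  expect_equal(cs2$sensitivity, 1)
  expect_equal(cs2$specificity, 0)

  set.seed(53)
  for (r in 1:10) {
    v3 <- rnorm(20); lab3 <- sample(c(TRUE, FALSE), 20, replace = TRUE, prob = c(.6, .4))
    if (length(unique(lab3)) < 2) next
    cs3 <- confusion_stats(v3, lab3, median(v3))
    expect_equal(cs3$accuracy,
                 (cs3$tp + cs3$tn) / (cs3$tp + cs3$tn + cs3$fp + cs3$fn))
  }
})

test_that("the 2-D rule calls non-apneic only in the low-low region", {
  feats <- tibble::tibble(
    subject_id = sprintf("s%d", 1:6),
    group = c("C", "C", "HT", "NT", "HT", "NT"),
    mean_L = c(100, 120, 400, 390, 110, 500),
    a_max = c(10, 12, 40, 45, 50, 11)
  )
  r <- rule2d_evaluate(feats, threshold_L = 200, threshold_A = 20)
  # below both thresholds -> non-apneic; either high -> apneic
  expect_equal(r$predicted, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(glance(r)$accuracy, 1)

  # thresholds at +Inf: everyone non-apneic
  rinf <- rule2d_evaluate(feats, threshold_L = Inf, threshold_A = Inf)
  expect_false(any(rinf$predicted))

  # OR variant requires both features to exceed
  ror <- rule2d_evaluate(feats, threshold_L = 200, threshold_A = 20, combine = "or")
  expect_equal(ror$predicted, c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))

  # missing features are skipped with a warning
  feats$a_max[3] <- NA
  expect_warning(r2 <- rule2d_evaluate(feats, threshold_L = 200, threshold_A = 20),
                 "skipping 1 subject")
  expect_equal(nrow(r2), 5L)
})

test_that("single-class input is rejected", {
  df <- tibble::tibble(v = rnorm(5), apneic = rep(TRUE, 5))
  expect_error(roc_curve(df, v, apneic), "both classes")
})

test_that("jointly optimized 2-D thresholds dominate both 1-D rules", {
  set.seed(61)
  for (r in 1:5) {
    feats <- tibble::tibble(
      subject_id = sprintf("s%d", 1:20),
      apneic = rep(c(TRUE, FALSE), c(13, 7)),
      mean_L = c(rnorm(13, 2), rnorm(7)),
      a_max = c(rnorm(13, 1.2), rnorm(7))
    )
    opt <- rule2d_evaluate(feats, optimize = TRUE)
    acc_L <- glance(roc_curve(feats, mean_L, apneic))$accuracy
    acc_A <- glance(roc_curve(feats, a_max, apneic))$accuracy
    expect_gte(glance(opt)$accuracy, max(acc_L, acc_A))
    # default rule uses the per-feature ROC thresholds
    def <- rule2d_evaluate(feats)
    expect_equal(glance(def)$threshold_L,
                 optimal_threshold(roc_curve(feats, mean_L, apneic)))
  }
})
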