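# Confusion counts, the six derived metrics and cohort aggregation.

test_that("confusion counts match identity and complement closed forms", {
  gt <- array(0L, c(10, 10, 1))
  gt[1:2, 1:5, 1] <- 1L                      # 10 foreground of 100
  cc <- confusion_counts(gt, gt)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               c(TP = 10L, TN = 90L, FP = 0L, FN = 0L))
  cc2 <- confusion_counts(1L - gt, gt)
  expect_equal(unclass(cc2)[c("TP", "TN", "FP", "FN")],
               c(TP = 0L, TN = 0L, FP = 90L, FN = 10L))
  expect_error(confusion_counts(gt, array(0L, c(5, 5, 1))), "shape")
  expect_error(confusion_counts(gt * 2L, gt), "binary")
})

test_that("counts and metrics agree with the per-voxel loop oracle", {
  set.seed(11)
  for (i in 1:25) {
    d <- c(sample(4:12, 1), sample(4:12, 1), sample(2:4, 1))
    pred <- array(rbinom(prod(d), 1, runif(1, 0.05, 0.6)), d)
    gt <- array(rbinom(prod(d), 1, runif(1, 0.05, 0.6)), d)
    cc <- confusion_counts(pred, gt)
    expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
                 oracle_confusion(pred, gt))
    m <- compute_metrics(cc)
    om <- oracle_metrics(cc)
    for (nm in names(om)) expect_equal(m[[nm]], om[[nm]], tolerance = 1e-12)
  }
})

test_that("the worked confusion example reproduces its six metrics", {
  m <- compute_metrics(c(TP = 2, TN = 96, FP = 1, FN = 1))
  expect_equal(round(m$dsc, 2), 66.67)
  expect_equal(round(m$accuracy, 2), 98.00)
  expect_equal(round(m$sensitivity, 2), 66.67)
  expect_equal(round(m$specificity, 2), 98.97)
  expect_equal(round(m$ppv, 2), 66.67)
  expect_equal(round(m$npv, 2), 98.97)
})

test_that("perfect prediction scores 100 everywhere; zero denominators are NA", {
  gt <- array(c(1L, 0L, 1L, 0L), c(2, 2, 1))
  m <- compute_metrics(confusion_counts(gt, gt))
  expect_true(all(unlist(m[menseg:::METRIC_NAMES]) == 100))
  empty <- array(0L, c(3, 3, 1))
  m0 <- compute_metrics(confusion_counts(empty, empty))
  expect_true(is.na(m0$dsc) && is.na(m0$sensitivity) && is.na(m0$ppv))
  expect_equal(c(m0$specificity, m0$npv, m0$accuracy), c(100, 100, 100))
})

test_that("metric symmetries hold: DSC swap and complement exchange", {
  set.seed(12)
  for (i in 1:10) {
    pred <- array(rbinom(256, 1, 0.3), c(8, 8, 4))
    gt <- array(rbinom(256, 1, 0.3), c(8, 8, 4))
    a <- compute_metrics(confusion_counts(pred, gt))
    b <- compute_metrics(confusion_counts(gt, pred))
    expect_equal(a$dsc, b$dsc)
    comp <- compute_metrics(confusion_counts(1L - pred, 1L - gt))
    expect_equal(a$accuracy, comp$accuracy)
    expect_equal(a$sensitivity, comp$specificity)
    expect_equal(a$ppv, comp$npv)
    # harmonic-mean identity when all terms are defined
    if (!is.na(a$dsc) && !is.na(a$ppv) && !is.na(a$sensitivity) &&
        (a$ppv + a$sensitivity) > 0) {
      expect_equal(a$dsc, 2 * a$ppv * a$sensitivity / (a$ppv + a$sensitivity),
                   tolerance = 1e-9)
    }
  }
})

test_that("cohort aggregation uses sample std and skips undefined entries", {
  reports <- dplyr::bind_rows(
    compute_metrics(c(TP = 8, TN = 92, FP = 2, FN = 2)),   # dsc 80
    compute_metrics(c(TP = 9, TN = 90, FP = 1, FN = 1)))   # dsc 90
  s <- aggregate_cohort(reports, side = "medial")
  dsc <- s[s$metric == "dsc", ]
  expect_equal(dsc$mean, 85)
  expect_equal(round(dsc$sd, 2), 7.07)
  expect_equal(dsc$side, "medial")

  same <- dplyr::bind_rows(reports[1, ], reports[1, ])
  expect_true(all(aggregate_cohort(same)$sd == 0))

  with_na <- reports
  with_na$ppv[2] <- NA_real_
  s2 <- aggregate_cohort(with_na)
  expect_equal(s2$n_defined[s2$metric == "ppv"], 1L)
  expect_true(is.na(s2$sd[s2$metric == "ppv"]))
  expect_error(aggregate_cohort(reports[1, ]), "at least 2")
})

test_that("cohort formatting follows the mean (±sd) convention", {
  reports <- dplyr::bind_rows(
    compute_metrics(c(TP = 8, TN = 92, FP = 2, FN = 2)),
    compute_metrics(c(TP = 9, TN = 90, FP = 1, FN = 1)))
  f <- format_cohort(aggregate_cohort(reports))
  expect_match(f$value[f$metric == "dsc"], "^85\\.00 \\(±7\\.07\\)$")
})
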