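test_that("confusion counting uses malignant as the positive class", {
  lab <- c(rep("malignant", 7), rep("benign", 3))
  cc <- confusionCounts(lab, lab)
  expect_equal(c(cc@tp, cc@fp, cc@tn, cc@fn), c(7L, 0L, 3L, 0L))
  allMal <- confusionCounts(lab, rep("malignant", 10))
  expect_equal(c(allMal@tp, allMal@fp, allMal@tn, allMal@fn),
               c(7L, 3L, 0L, 0L))
  expect_error(confusionCounts(character(), character()), "empty")
  expect_error(confusionCounts(lab, lab[-1]), "length")
})

test_that("metric report matches definition arithmetic on the rate convention", {
  cc <- new("ConfusionCounts", tp = 91L, fn = 9L, tn = 86L, fp = 14L)
  r <- metricReport(cc)
  expect_equal(r@sensitivity, 91)
  expect_equal(r@specificity, 86)
  expect_equal(r@fpRate, 14)
  expect_equal(r@fnRate, 9)
  perfect <- metricReport(new("ConfusionCounts", tp = 5L, fn = 0L,
                              tn = 5L, fp = 0L))
  expect_equal(perfect@mcc, 1)
  expect_equal(perfect@fMeasure, 100)
  balanced <- metricReport(new("ConfusionCounts", tp = 50L, fp = 50L,
                               tn = 50L, fn = 50L))
  expect_equal(balanced@mcc, 0)
  expect_equal(balanced@accuracy, 50)
  expect_error(metricReport(new("ConfusionCounts", tp = 0L, fn = 0L,
                                tn = 5L, fp = 1L)), "positives")
  expect_warning(
    r0 <- metricReport(new("ConfusionCounts", tp = 0L, fn = 5L, tn = 3L,
                           fp = 0L)), "precision")
  expect_equal(r0@precision, 0)
  expect_true(r0@precisionUndefined)
})

test_that("report agrees with brute force on exhaustive small confusion matrices", {
  # every matrix with n <= 14 and both actual classes present
  for (n in 2:14) {
    for (tp in 0:n) for (fp in 0:(n - tp)) for (tn in 0:(n - tp - fp)) {
      fn <- n - tp - fp - tn
      if (tp + fn == 0L || tn + fp == 0L) next
      r <- suppressWarnings(metricReport(new("ConfusionCounts",
                                             tp = tp, fp = fp,
                                             tn = tn, fn = fn)))
      b <- bruteMetrics(tp, fp, tn, fn)
      expect_equal(r@sensitivity, b$sens)
      expect_equal(r@specificity, b$spec)
      expect_equal(r@accuracy, b$acc)
      expect_equal(r@precision, b$prec)
      expect_equal(r@fMeasure, b$f)
      expect_equal(r@mcc, b$mcc)
      expect_true(r@mcc >= -1 && r@mcc <= 1)
      expect_equal(r@sensitivity + r@fnRate, 100)
      expect_equal(r@specificity + r@fpRate, 100)
      if (r@precision > 0 && r@recall > 0) {
        expect_lte(r@fMeasure, max(r@precision, r@recall) + 1e-9)
        expect_gte(r@fMeasure, min(r@precision, r@recall) - 1e-9)
      }
      if (tp > 0 && fp > 0 && tn > 0 && fn > 0) {
        expect_true(abs(r@mcc) < 1)
      }
    }
  }
})

test_that("swapping the positive-class convention mirrors the report", {
  set.seed(12)
  lab <- sample(c("benign", "malignant"), 60, replace = TRUE,
                prob = c(0.4, 0.6))
  pred <- sample(c("benign", "malignant"), 60, replace = TRUE)
  r <- metricReport(confusionCounts(lab, pred))
  flip <- function(x) ifelse(x == "benign", "malignant", "benign")
  rf <- metricReport(confusionCounts(flip(lab), flip(pred)))
  expect_equal(rf@sensitivity, r@specificity)
  expect_equal(rf@specificity, r@sensitivity)
  expect_equal(rf@accuracy, r@accuracy)
  expect_equal(abs(rf@mcc), abs(r@mcc))
})
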