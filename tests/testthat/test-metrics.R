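test_that("confusion matrix tallies exactly", {
  cm <- confusion(c("a", "b", "a"), c("a", "b", "a"))
  expect_equal(unname(diag(unclass(cm))), c(2, 1))
  expect_equal(sum(cm), 3)

  cm2 <- confusion(c(1, 1, 0, 0), c(1, 0, 1, 0), levels = c("0", "1"))
  ct <- gaitbouts:::binary_counts(cm2, "1")
  expect_equal(unname(ct), c(1, 1, 1, 1))  # TP TN FP FN

  expect_error(confusion(c("a", "b"), c("a")), "length")
})

test_that("confusion matches a brute-force tally on random label pairs", {
  set.seed(5)
  for (i in 1:20) {
    n <- 1000
    lev <- letters[1:sample(2:5, 1)]
    tr <- sample(lev, n, replace = TRUE)
    pr <- sample(lev, n, replace = TRUE)
    cm <- confusion(tr, pr, levels = lev)
    for (a in lev) for (b in lev) {
      expect_equal(unclass(cm)[a, b], sum(tr == a & pr == b))
    }
  }
})

test_that("the four metric formulas are exact", {
  # TP=TN>0, FP=FN=0 -> all ones
  cm <- confusion(c("w", "w", "n", "n"), c("w", "w", "n", "n"),
                  levels = c("n", "w"))
  r <- classification_metrics(cm, "w")
  expect_equal(c(r$accuracy, r$precision, r$recall, r$f1), rep(1, 4))

  # zero-denominator policy: no predicted positives -> precision NaN
  cm2 <- confusion(c("w", "n"), c("n", "n"), levels = c("n", "w"))
  expect_warning(r2 <- classification_metrics(cm2, "w"), "precision")
  expect_true(is.nan(r2$precision))
  expect_equal(r2$recall, 0)
})

test_that("metrics match closed-form oracles on 500 random confusion matrices", {
  set.seed(6)
  for (i in 1:500) {
    tp <- sample(0:50, 1); tn <- sample(0:50, 1)
    fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + tn + fp + fn == 0) next
    m <- matrix(c(tn, fp, fn, tp), 2, 2, byrow = TRUE,
                dimnames = list(c("n", "w"), c("n", "w")))
    cm <- structure(m, class = c("confusion_matrix", "matrix"))
    r <- suppressWarnings(classification_metrics(cm, "w"))
    expect_equal(r$accuracy, (tp + tn) / (tp + tn + fp + fn))
    if (tp + fp > 0) expect_equal(r$precision, tp / (tp + fp))
    if (tp + fn > 0) expect_equal(r$recall, tp / (tp + fn))
    if (2 * tp + fp + fn > 0) {
      expect_equal(r$f1, 2 * tp / (2 * tp + fp + fn))
      # F1 is the harmonic mean of precision and recall when both defined
      if (tp + fp > 0 && tp + fn > 0 && tp > 0) {
        expect_equal(r$f1, 2 * r$precision * r$recall /
                       (r$precision + r$recall), tolerance = 1e-9)
      }
      expect_lte(r$f1, max(r$precision, r$recall, na.rm = TRUE) + 1e-12)
      expect_equal(r$f1 == 0, tp == 0)
    }
  }
})

test_that("wilson_interval matches the closed form on 500 random inputs", {
  set.seed(7)
  for (i in 1:500) {
    n <- sample(1:500, 1)
    k <- sample(0:n, 1)
    got <- wilson_interval(k, n)
    want <- wilson_oracle(k, n)
    expect_equal(got, want, tolerance = 1e-12)
    expect_gte(got[1], 0); expect_lte(got[2], 1)
    expect_gte(k / n, got[1] - 1e-12)
    expect_lte(k / n, got[2] + 1e-12)
  }
  expect_equal(wilson_interval(0, 10)[1], 0)
  expect_error(wilson_interval(1, 0), "positive")
  expect_error(wilson_interval(5, 3), "\\[0, n\\]")
})

test_that("mask_report equals the confusion+metrics composition", {
  set.seed(8)
  n <- 10000
  tv <- runif(n) > 0.5
  pv <- runif(n) > 0.5
  truth <- gait_mask(tv, 100, "truth")
  pred <- gait_mask(pv, 100, "freq")
  r <- mask_report(truth, pred)
  cm <- confusion(ifelse(tv, "walking", "not_walking"),
                  ifelse(pv, "walking", "not_walking"),
                  levels = c("not_walking", "walking"))
  r2 <- classification_metrics(cm, "walking")
  expect_equal(r[c("accuracy", "precision", "recall", "f1")],
               r2[c("accuracy", "precision", "recall", "f1")])

  expect_equal(mask_report(truth, truth)$accuracy, 1)
  inv <- gait_mask(!tv, 100, "freq")
  expect_equal(mask_report(truth, inv)$accuracy, 0)
  expect_equal(mask_report(truth, inv)$recall, 0)

  # validity restriction
  valid <- rep(c(TRUE, FALSE), n / 2)
  rv <- mask_report(truth, pred, valid)
  expect_equal(rv$n, sum(valid))
  expect_error(mask_report(truth, pred, rep(FALSE, n)), "no valid samples")
})

test_that("per-class one-vs-rest agrees with collapsed binary metrics", {
  set.seed(9)
  lev <- c("static", "walking", "other")
  tr <- sample(lev, 500, replace = TRUE)
  pr <- sample(lev, 500, replace = TRUE)
  cm <- confusion(tr, pr, levels = lev)
  pc <- suppressWarnings(per_class_metrics(cm, wilson = FALSE))
  for (cl in lev) {
    bm <- classification_metrics(
      confusion(ifelse(tr == cl, cl, "rest"), ifelse(pr == cl, cl, "rest"),
                levels = c("rest", cl)), cl)
    expect_equal(pc[[cl]]$precision, bm$precision)
    expect_equal(pc[[cl]]$recall, bm$recall)
    expect_equal(pc[[cl]]$f1, bm$f1)
  }
})

test_that("median aggregation across participants", {
  reps <- lapply(c(0.8, 0.9, 1.0), function(a) {
    structure(list(accuracy = a, precision = a, recall = a, f1 = a,
                   n = 10L), class = "metrics_report")
  })
  m <- median_report(reps)
  expect_equal(m$accuracy, 0.9)
  expect_equal(m$n, 30)
})
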