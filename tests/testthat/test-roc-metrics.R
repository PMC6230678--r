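test_that("AUC equals exhaustive pair counting and handles ties", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(c(1, 3, 2, 4), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")

  pair_count <- function(s, l) {
    pos <- s[l == 1]; neg <- s[l == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  set.seed(10)
  for (rep in 1:25) {
    s <- sample(20, 15, replace = TRUE)  # plenty of ties
    l <- rbinom(15, 1, 0.5)
    if (sum(l) %in% c(0, 15)) next
    expect_equal(auc(s, l), pair_count(s, l), tolerance = 1e-12)
  }
})

test_that("AUC equals the trapezoidal area under the operating points", {
  trapezoid <- function(s, l) {
    pts <- roc_points(s, l)
    # points run from (0,0); integrate sens over fpr
    sum(diff(pts$fpr) * (head(pts$sensitivity, -1) + tail(pts$sensitivity, -1)) / 2)
  }
  set.seed(11)
  for (rep in 1:25) {
    s <- c(rnorm(8), rnorm(7, 1))
    l <- rep(c(0, 1), c(8, 7))
    expect_equal(auc(s, l), trapezoid(s, l), tolerance = 1e-12)
    expect_equal(auc(s, l) + auc(-s, l), 1, tolerance = 1e-12)  # tie-free
    pts <- roc_points(s, l)
    expect_true(all(diff(pts$sensitivity) >= 0))
    expect_true(all(diff(pts$fpr) >= 0))
    expect_equal(c(pts$sensitivity[1], pts$fpr[1]), c(0, 0))
    expect_equal(c(tail(pts$sensitivity, 1), tail(pts$fpr, 1)), c(1, 1))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  for (rep in 1:10) {
    s <- rnorm(30); l <- rbinom(30, 1, 0.4)
    if (sum(l) %in% c(0, 30)) next
    ref <- suppressMessages(as.numeric(pROC::auc(l, s, direction = "<")))
    expect_equal(auc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE matches closed forms and is monotone in n", {
  expect_lt(abs(auc_se_hanley_mcneil(0.99, 14, 13) - 0.02), 0.005)
  expect_equal(auc_se_hanley_mcneil(1, 10, 10), 0)
  expect_equal(auc_se_hanley_mcneil(0.5, 1, 1), 0.5)
  se <- vapply(5:50, function(n) auc_se_hanley_mcneil(0.8, n, 20), numeric(1))
  expect_true(all(diff(se) < 0))
  se2 <- vapply(5:50, function(n) auc_se_hanley_mcneil(0.8, 20, n), numeric(1))
  expect_true(all(diff(se2) < 0))
})

test_that("cutoff selection follows the stated policies", {
  # separated classes: midpoint of the gap
  expect_equal(select_cutoff(c(0, 1, 2, 3), c(0, 0, 1, 1), "youden"), 1.5)

  # max-specificity keeps specificity 1, maximizing sensitivity: pos
  # {0.5, 2, 3}, neg {0, 1} -> cutoff in (1, 2), sensitivity 2/3
  s <- c(0.5, 2, 3, 0, 1); l <- c(1, 1, 1, 0, 0)
  cut <- select_cutoff(s, l, "max_specificity")
  expect_equal(cut, 1.5)
  cm <- confusion_metrics(call_fi(s, cut), l)
  expect_equal(cm$sensitivity, 2 / 3)
  expect_equal(cm$specificity, 1)

  # exhaustive check: no candidate beats the returned Youden cutoff
  set.seed(13)
  for (rep in 1:20) {
    s <- round(rnorm(20), 1); l <- rbinom(20, 1, 0.5)
    if (sum(l) %in% c(0, 20)) next
    cut <- select_cutoff(s, l, "youden")
    J <- function(t) {
      cm <- confusion_metrics(s >= t, l)
      cm$sensitivity + cm$specificity - 1
    }
    expect_gte(J(cut) + 1e-12, max(vapply(sort(unique(s)), J, numeric(1))))
  }

  # all negatives above positives: only the above-everything cutoff has spec 1
  s2 <- c(1, 2, 10, 11); l2 <- c(1, 1, 0, 0)
  cut2 <- select_cutoff(s2, l2, "max_specificity")
  expect_gt(cut2, 11)
})

test_that("label flip with score negation negates the cutoff", {
  set.seed(14)
  for (rep in 1:10) {
    s <- rnorm(16); l <- rep(c(0, 1), 8)
    cut <- select_cutoff(s, l, "youden")
    cut_flip <- select_cutoff(-s, 1 - l, "youden")
    # compare achieved operating points (the optimum may be a tie set)
    cm <- confusion_metrics(s >= cut, l)
    cm_f <- confusion_metrics(-s >= cut_flip, 1 - l)
    expect_equal(cm_f$sensitivity + cm_f$specificity,
                 cm$sensitivity + cm$specificity, tolerance = 1e-12)
  }
  # unique-optimum case: exact negation
  expect_equal(select_cutoff(c(-3, -2, -1, 0), c(0, 0, 1, 1), "youden"),
               -select_cutoff(c(3, 2, 1, 0), c(1, 1, 0, 0), "youden"))
})

test_that("confusion metrics match the printed worked example", {
  # 14 FI patients (13 called) vs 13 without (0 called)
  calls <- c(rep(TRUE, 13), FALSE, rep(FALSE, 13))
  labels <- c(rep(TRUE, 14), rep(FALSE, 13))
  cm <- confusion_metrics(calls, labels)
  expect_equal(cm$sensitivity, 0.9286, tolerance = 1e-4)
  expect_equal(cm$specificity, 1)
  expect_equal(cm$ppv, 1)
  expect_equal(cm$npv, 0.9286, tolerance = 1e-4)

  all_right <- confusion_metrics(labels, labels)
  expect_equal(c(all_right$sensitivity, all_right$specificity,
                 all_right$ppv, all_right$npv), rep(1, 4))

  none <- confusion_metrics(rep(FALSE, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_true(is.na(none$ppv))   # undefined, not zero
  expect_equal(none$specificity, 1)
})
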