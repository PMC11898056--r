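test_that("confusion counts reproduce hand counts, including all n = 4 patterns", {
  cc <- confusion_counts(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")],
                   list(TP = 2L, TN = 2L, FP = 0L, FN = 0L))
  cc <- confusion_counts(c(1, 0), c(0, 1))
  expect_identical(c(cc$FP, cc$FN), c(1L, 1L))
  cc <- confusion_counts(c(1, 1, 1, 0), c(1, 0, 1, 0))
  expect_identical(c(cc$TP, cc$TN, cc$FP, cc$FN), c(2L, 1L, 1L, 0L))
  # exhaustive: all 2^4 prediction patterns against a fixed truth
  truth <- c(1, 0, 1, 0)
  for (m in 0:15) {
    pred <- as.integer(intToBits(m)[1:4])
    cc <- confusion_counts(pred, truth)
    expect_identical(cc$TP, sum(pred == 1 & truth == 1))
    expect_identical(cc$TN, sum(pred == 0 & truth == 0))
    expect_identical(cc$FP, sum(pred == 1 & truth == 0))
    expect_identical(cc$FN, sum(pred == 0 & truth == 1))
    expect_identical(cc$TP + cc$TN + cc$FP + cc$FN, 4L)
    expect_equal(accuracy(cc), mean(pred == truth))
  }
  expect_error(confusion_counts(c(1, 0), c(1, 0, 1)), "lengths")
})

test_that("accuracy and precision follow their defining ratios", {
  expect_identical(accuracy(confusion_counts(c(1, 0), c(1, 0))), 1)
  expect_identical(accuracy(confusion_counts(c(1, 0), c(0, 1))), 0)
  cc <- list(TP = 3L, TN = 5L, FP = 1L, FN = 1L)
  expect_equal(accuracy(cc), 0.8)
  expect_equal(precision(list(TP = 3L, FP = 1L)), 0.75)
  expect_identical(precision(list(TP = 2L, FP = 0L)), 1)
  expect_identical(precision(list(TP = 0L, FP = 3L)), 0)
  expect_warning(p <- precision(list(TP = 0L, FP = 0L)), "undefined")
  expect_true(is.na(p))
})

test_that("ROC curve is anchored, monotone, and hits the forced corners", {
  r <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(r$fpr[1], 0); expect_identical(r$tpr[1], 0)
  expect_identical(r$fpr[length(r$fpr)], 1)
  expect_identical(r$tpr[length(r$tpr)], 1)
  expect_true(any(r$fpr == 0 & r$tpr == 1))       # perfect separation
  r2 <- roc_curve(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))
  expect_true(any(r2$fpr == 1 & r2$tpr == 0))     # reversed scores
  expect_true(all(diff(r$fpr) >= 0))
  expect_error(roc_curve(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals brute-force pair counting with half credit for ties", {
  expect_identical(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(auc(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_equal(auc(c(0.9, 0.4, 0.7, 0.6), c(1, 1, 0, 0)), 0.5)
  set.seed(61)
  for (trial in 1:200) {
    n <- sample(4:50, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)  # provoke ties
    pairs <- 0; wins <- 0
    for (i in which(truth == 1)) for (j in which(truth == 0)) {
      pairs <- pairs + 1
      wins <- wins + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
    }
    expect_equal(auc(scores, truth), wins / pairs, tolerance = 1e-12)
    # and equals the trapezoidal area under the ROC curve
    r <- roc_curve(scores, truth)
    expect_equal(auc(scores, truth), stabnet:::trapezoid_area(r$fpr, r$tpr),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly increasing score transforms", {
  set.seed(62)
  scores <- rnorm(30); truth <- sample(0:1, 30, replace = TRUE)
  truth[1:2] <- c(0, 1)
  a <- auc(scores, truth)
  expect_equal(auc(exp(scores), truth), a, tolerance = 1e-12)
  expect_equal(auc(qlogis(plogis(scores)), truth), a, tolerance = 1e-9)
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(63)
  for (trial in 1:20) {
    n <- sample(10:40, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)
    ref <- suppressMessages(as.numeric(pROC::auc(truth, scores,
                                                 direction = "<", quiet = TRUE)))
    expect_equal(auc(scores, truth), ref, tolerance = 1e-12)
  }
})

test_that("macro ROC averages one-vs-rest AUCs and detects missing classes", {
  set.seed(64)
  n <- 100
  truth <- sample(0:2, n, replace = TRUE)
  scores <- matrix(rnorm(3 * n), n, 3)
  scores[cbind(1:n, truth + 1)] <- scores[cbind(1:n, truth + 1)] + 5
  m <- macro_roc_auc(scores, truth)
  expect_identical(m$macro_auc, 1)
  expect_identical(m$per_class_auc, rep(1, 3))
  expect_equal(m$macro_auc, mean(m$per_class_auc))
  # binary symmetry: class-0 AUC on class-0 scores complements class-1
  s2 <- cbind(rnorm(40), rnorm(40))
  t2 <- c(0, 1, sample(0:1, 38, replace = TRUE))
  m2 <- macro_roc_auc(s2, t2)
  expect_equal(m2$per_class_auc[1], 1 - auc(s2[, 1], as.integer(t2 == 1)),
               tolerance = 1e-12)
  expect_error(macro_roc_auc(scores, pmin(truth, 1)), "absent")
})

test_that("macro AUC of uninformative scores sits at one half", {
  set.seed(65)
  n <- 2000
  truth <- sample(0:4, n, replace = TRUE)
  scores <- matrix(runif(5 * n), n, 5)
  m <- macro_roc_auc(scores, truth)
  expect_lt(abs(m$macro_auc - 0.5), 0.03)
})

test_that("correlation and fit metrics match their defining arithmetic", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  expect_identical(pearson(x, x), 1)
  expect_equal(pearson(x, 3 - 2 * x), -1, tolerance = 1e-12)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson(x, y), direct, tolerance = 1e-12)
  expect_error(pearson(c(1, 1), c(1, 2)), "zero-variance")

  expect_equal(spearman(sort(rnorm(10)), exp(sort(rnorm(10)))), 1,
               tolerance = 1e-12)
  expect_equal(spearman(c(1, 2, 3), c(2, 1, 3)), 1 - 6 * 2 / (3 * 8),
               tolerance = 1e-12)
  set.seed(66)
  xt <- sample(1:5, 20, replace = TRUE); yt <- sample(1:5, 20, replace = TRUE)
  expect_equal(spearman(xt, yt), pearson(rank(xt), rank(yt)), tolerance = 1e-12)

  expect_identical(r_squared(y, y), 1)
  expect_identical(r_squared(y, rep(mean(y), 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5, tolerance = 1e-12)
  expect_lt(r_squared(c(1, 2, 3), c(10, -4, 7)), 0)  # bad fits go negative
  expect_error(r_squared(c(2, 2), c(1, 2)), "constant")
})

test_that("paired-sample metrics are permutation invariant", {
  set.seed(67)
  x <- rnorm(25); y <- x + rnorm(25)
  pi_ <- sample(25)
  expect_equal(pearson(x[pi_], y[pi_]), pearson(x, y), tolerance = 1e-12)
  expect_equal(spearman(x[pi_], y[pi_]), spearman(x, y), tolerance = 1e-12)
  expect_equal(r_squared(x[pi_], y[pi_]), r_squared(x, y), tolerance = 1e-12)
})
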