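# Confusion counts, rate metrics, ROC/AUC and cross-validation.

test_that("confusion counts match hand tallies", {
  lab <- c(rep("active", 4), rep("inactive", 6))
  pred <- c("active", "active", "inactive", "active",
            "inactive", "active", "inactive", "inactive", "inactive", "active")
  cm <- confusionCounts(lab, pred)
  expect_equal(cm, c(TP = 3L, FP = 2L, TN = 4L, FN = 1L))

  expect_equal(confusionCounts(lab, lab)[c("FP", "FN")], c(FP = 0L, FN = 0L))
  allwrong <- confusionCounts(rep("active", 5), rep("inactive", 5))
  expect_equal(unname(allwrong[c("TP", "FN")]), c(0L, 5L))
  expect_error(confusionCounts("active", c("active", "inactive")), "equal length")
})

test_that("metrics implement the stated definitions", {
  met <- classificationMetrics(c(TP = 60, FN = 40, FP = 19, TN = 81))
  expect_equal(unname(met["TPR"]), 0.60)
  expect_equal(unname(met["FPR"]), 0.19)
  expect_equal(unname(met["sensitivity"]), 0.60)
  expect_equal(unname(met["specificity"]), 0.81)
  expect_equal(unname(met["accuracy"]), 141 / 200)
  expect_equal(unname(met["BCR"]), 0.705)

  perfect <- classificationMetrics(c(TP = 5, FN = 0, FP = 0, TN = 5))
  expect_equal(unname(perfect[c("accuracy", "BCR")]), c(1, 1))

  # empty classes yield NaN with a warning, never a silent zero
  expect_warning(m <- classificationMetrics(c(TP = 0, FN = 0, FP = 1, TN = 9)),
                 "positives")
  expect_true(is.nan(m[["TPR"]]))
})

test_that("BCR of a classifier and its label-flip complement sum to 1", {
  set.seed(8)
  lab <- sample(c("active", "inactive"), 60, replace = TRUE, prob = c(.3, .7))
  pred <- sample(c("active", "inactive"), 60, replace = TRUE)
  flip <- ifelse(pred == "active", "inactive", "active")
  b1 <- classificationMetrics(confusionCounts(lab, pred))[["BCR"]]
  b2 <- classificationMetrics(confusionCounts(lab, flip))[["BCR"]]
  expect_equal(b1 + b2, 1)
})

test_that("coin-flip predictions on balanced data give BCR near 0.5", {
  set.seed(9)
  lab <- rep(c("active", "inactive"), each = 5000)
  pred <- sample(c("active", "inactive"), 10000, replace = TRUE)
  expect_equal(classificationMetrics(confusionCounts(lab, pred))[["BCR"]],
               0.5, tolerance = 0.02)
})

test_that("ROC/AUC matches the all-pairs Mann-Whitney statistic", {
  # perfectly ranked scores
  lab8 <- rep(c("active", "inactive"), each = 4)
  expect_equal(rocAuc(lab8, c(4, 3, 2, 1.5, 1, .5, .2, .1))$auc, 1.0)

  # 8-record toy with ties, against the pair-counting oracle
  sc <- c(3, 2, 2, 1, 2, 1, 0.5, 0.5)
  expect_equal(rocAuc(lab8, sc)$auc, oracleAuc(lab8, sc))

  # 50 random small score sets
  set.seed(10)
  for (rep in 1:50) {
    n <- sample(6:20, 1)
    lab <- sample(c("active", "inactive"), n, replace = TRUE)
    if (length(unique(lab)) < 2) lab <- c("active", "inactive", lab[-(1:2)])
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)
    expect_equal(rocAuc(lab, s)$auc, oracleAuc(lab, s), tolerance = 1e-12)
  }
  expect_error(rocAuc(rep("active", 4), 1:4), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(11)
  lab <- sample(c("active", "inactive"), 40, replace = TRUE)
  lab[1:2] <- c("active", "inactive")
  s <- rnorm(40)
  a0 <- rocAuc(lab, s)$auc
  expect_equal(rocAuc(lab, exp(s))$auc, a0)
  expect_equal(rocAuc(lab, 3 * s - 7)$auc, a0)
})

test_that("labels independent of scores give AUC near 0.5", {
  set.seed(12)
  lab <- sample(c("active", "inactive"), 4000, replace = TRUE)
  expect_equal(rocAuc(lab, rnorm(4000))$auc, 0.5, tolerance = 0.03)
})

test_that("cross-validation partitions records and conserves counts", {
  set.seed(13)
  x <- matrix(rbinom(60 * 5, 1, 0.5), 60, 5,
              dimnames = list(NULL, paste0("b", 1:5)))
  lab <- rep(c("active", "inactive"), each = 30)
  x[lab == "active", 1] <- rbinom(30, 1, 0.9)
  trainer <- function(x, l) trainNaiveBayes(x, l)
  cv <- crossValidate(x, lab, k = 5, train = trainer, seed = 3)
  expect_equal(sum(cv$pooled), 60L)                    # conservation
  expect_equal(sort(unique(cv$fold)), 1:5)
  expect_true(all(table(cv$fold, lab) == 6))           # stratified
  cv2 <- crossValidate(x, lab, k = 5, train = trainer, seed = 3)
  expect_identical(cv$fold, cv2$fold)                  # same seed, same folds

  # leave-one-out on a tiny balanced set: every record tested exactly once
  x10 <- x[1:10, ]; lab10 <- rep(c("active", "inactive"), 5)
  cvl <- crossValidate(x10, lab10, k = 5, train = trainer, seed = 1)
  expect_equal(as.integer(table(cvl$fold)), rep(2L, 5))
  expect_error(crossValidate(x10, lab10, k = 6, train = trainer), "at least k")
})

test_that("our AUC agrees with pROC on a random problem", {
  skip_if_not_installed("pROC")
  set.seed(14)
  lab <- sample(c("active", "inactive"), 300, replace = TRUE)
  s <- rnorm(300) + (lab == "active")
  ours <- rocAuc(lab, s)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = s,
                                        levels = c("inactive", "active"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
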