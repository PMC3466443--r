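# Naive Bayes, random forest contract, cost-sensitive decisions and the
# FP-capped cost search.

test_that("Naive Bayes training matches hand-computed smoothed estimates", {
  x <- cbind(bit = c(1, 1, 0, 0))
  lab <- c("active", "active", "inactive", "inactive")
  m <- trainNaiveBayes(x, lab)
  expect_equal(m@p1["active", "bit"], 3 / 4)     # (2+1)/(2+2), Laplace alpha=1
  expect_equal(m@p1["inactive", "bit"], 1 / 4)
  expect_equal(unname(m@priors), c(0.5, 0.5))    # equal class sizes

  # constant continuous column within a class: sigma clamps, no error
  x2 <- cbind(val = c(1, 1, 2, 3))
  m2 <- trainNaiveBayes(x2, lab, binary = FALSE)
  expect_equal(m2@sigma["active", "val"], 1e-9)
  expect_true(is.finite(nbPosterior(m2, cbind(val = 1))))

  expect_error(trainNaiveBayes(x, rep("active", 4)), "both classes")
})

test_that("posterior equals the prior for an uninformative model", {
  # identical likelihoods per class: every row the same in both classes
  x <- cbind(b1 = rep(1, 6), b2 = rep(0, 6))
  lab <- rep(c("active", "inactive"), 3)
  m <- trainNaiveBayes(x, lab)
  expect_equal(nbPosterior(m, cbind(b1 = 1, b2 = 0)), 0.5, tolerance = 1e-12)
})

test_that("a single separating bit gives the closed-form smoothed posterior", {
  x <- cbind(bit = c(1, 1, 0, 0))
  lab <- c("active", "active", "inactive", "inactive")
  m <- trainNaiveBayes(x, lab)
  # P(a|bit=1) = .5*.75 / (.5*.75 + .5*.25) = 0.75: bounded away from 1 only
  # by the smoothing
  expect_equal(nbPosterior(m, cbind(bit = 1)), 0.75, tolerance = 1e-12)
  expect_equal(nbPosterior(m, cbind(bit = 0)), 0.25, tolerance = 1e-12)
})

test_that("log-space posterior equals the direct product formula", {
  set.seed(21)
  directPosterior <- function(m, xrow) {
    pa <- m@priors[["active"]]; pi <- m@priors[["inactive"]]
    for (j in seq_along(m@columns)) {
      p1a <- m@p1["active", j]; p1i <- m@p1["inactive", j]
      pa <- pa * ifelse(xrow[j] == 1, p1a, 1 - p1a)
      pi <- pi * ifelse(xrow[j] == 1, p1i, 1 - p1i)
    }
    pa / (pa + pi)
  }
  for (rep in 1:5) {
    x <- matrix(rbinom(30 * 10, 1, runif(1, .2, .8)), 30, 10,
                dimnames = list(NULL, paste0("b", 1:10)))
    lab <- sample(c("active", "inactive"), 30, replace = TRUE)
    lab[1:2] <- c("active", "inactive")
    m <- trainNaiveBayes(x, lab)
    probe <- rbinom(10, 1, 0.5)
    names(probe) <- colnames(x)
    expect_equal(nbPosterior(m, t(probe)), unname(directPosterior(m, probe)),
                 tolerance = 1e-12)
  }
})

test_that("posteriors over the two classes sum to one", {
  set.seed(22)
  x <- matrix(rbinom(40 * 8, 1, 0.4), 40, 8, dimnames = list(NULL, paste0("b", 1:8)))
  lab <- rep(c("active", "inactive"), 20)
  m <- trainNaiveBayes(x, lab)
  # swapping the class labels swaps the posterior
  mflip <- trainNaiveBayes(x, ifelse(lab == "active", "inactive", "active"))
  p <- nbPosterior(m, x)
  pflip <- nbPosterior(mflip, x)
  expect_equal(p + pflip, rep(1, 40), tolerance = 1e-12)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("NB model JSON serialization round trips", {
  set.seed(23)
  x <- cbind(matrix(rbinom(20 * 3, 1, .5), 20, 3), matrix(rnorm(20 * 2), 20, 2))
  colnames(x) <- c(paste0("b", 1:3), paste0("c", 1:2))
  lab <- rep(c("active", "inactive"), 10)
  m <- trainNaiveBayes(x, lab)
  path <- tempfile(fileext = ".json")
  writeNBModel(m, path)
  back <- readNBModel(path)
  expect_equal(nbPosterior(back, x), nbPosterior(m, x), tolerance = 1e-12)
})

test_that("random forest separates a trivially separable toy and is seeded", {
  set.seed(24)
  x <- cbind(sig = rep(c(1, 0), each = 25),
             noise = rbinom(50, 1, 0.5))
  lab <- rep(c("active", "inactive"), each = 25)
  rf <- trainRandomForest(x, lab, seed = 7)
  pred <- ifelse(predictProb(rf, x) > 0.5, "active", "inactive")
  expect_equal(mean(pred == lab), 1.0)
  rf2 <- trainRandomForest(x, lab, seed = 7)
  expect_identical(predictProb(rf2, x), predictProb(rf, x))
  expect_error(trainRandomForest(x, rep("active", 50)), "both classes")
})

test_that("minimum-expected-cost decisions use the closed-form threshold", {
  expect_equal(costThreshold(costModel(1)), 0.5)
  expect_equal(costThreshold(costModel(38)), 1 / 39)
  p <- c(0.01, 1 / 39, 0.03, 0.6)
  expect_equal(costSensitivePredict(p, costModel(38)),
               c("inactive", "inactive", "active", "active"))  # tie -> inactive
  expect_equal(costSensitivePredict(c(0.5, 0.51), costModel(1)),
               c("inactive", "active"))
})

test_that("predicted-active count is non-decreasing in the FN cost", {
  set.seed(25)
  p <- runif(500)
  counts <- vapply(c(1, 2, 5, 10, 50, 1000),
                   function(cfn) sum(costSensitivePredict(p, costModel(cfn)) == "active"),
                   numeric(1))
  expect_false(is.unsorted(counts))
})

test_that("cost search respects the cap and its degenerate modes", {
  set.seed(26)
  sim <- simulateDescriptors(syntheticAssayConfig(n_actives = 60,
                                                  n_inactives = 600, seed = 4))
  x <- descriptorValues(sim$x)
  trainer <- function(x, l) trainNaiveBayes(x, l)
  # cap 1.0: the last (largest) scheduled cost is selected
  t1 <- tuneCost(x, sim$labels, train = trainer, fp_cap = 1.0, seed = 5)
  expect_equal(t1$cost@cost_fn, max(defaultCostSchedule()))
  # impossible cap: error naming the best infeasible point
  expect_error(tuneCost(x, sim$labels, train = trainer, fp_cap = -1e-9, seed = 5),
               "best infeasible")
  # schedule must increase strictly
  expect_error(tuneCost(x, sim$labels, train = trainer, schedule = c(5, 5)),
               "is.unsorted")
})

test_that("NB recovers planted descriptor effects (likelihood ratio and AUC)", {
  # actives carry informative bits with P=0.9 vs 0.1 in inactives
  eff <- data.frame(column = fingerprintColumnNames()[c(5, 25, 60)],
                    p_active = 0.9, p_inactive = 0.1)
  cfg <- syntheticAssayConfig(n_actives = 150, n_inactives = 1500,
                              effects = eff, seed = 6)
  sim <- simulateDescriptors(cfg)
  d <- data.frame(id = rownames(descriptorValues(sim$x)), class = sim$labels)
  sp <- splitTrainTest(d, test_fraction = 0.2, seed = 7)
  x <- descriptorValues(sim$x)
  m <- trainNaiveBayes(x[sp$train$id, ], sp$train$class, binary = binaryColumns(sim$x))
  # trained likelihood ratio for the planted bits exceeds 1 and beats noise
  lr <- m@p1["active", ] / m@p1["inactive", ]
  expect_true(all(lr[eff$column] > 1))
  expect_true(min(lr[eff$column]) > max(lr[setdiff(names(lr), eff$column)]))
  auc <- rocAuc(sp$test$class, nbPosterior(m, x[sp$test$id, ]))$auc
  expect_gt(auc, 0.85)
})

test_that("consensus screening is set algebra over per-model hits", {
  set.seed(27)
  x <- matrix(rbinom(40 * 6, 1, .5), 40, 6,
              dimnames = list(sprintf("cmp%02d", 1:40), paste0("b", 1:6)))
  lab <- rep(c("active", "inactive"), 20)
  m <- trainNaiveBayes(x, lab)
  same <- consensusScreen(list(a = m, b = m), x)
  expect_identical(same$consensus, same$per_model$a)   # identical models
  rf <- trainRandomForest(x, lab, seed = 1)
  both <- consensusScreen(list(nb = m, rf = rf), x)
  expect_true(all(both$consensus %in% both$per_model$nb))
  expect_true(all(both$consensus %in% both$per_model$rf))
  expect_lte(length(both$consensus),
             min(lengths(both$per_model)))
})
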