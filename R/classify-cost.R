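# Cost-sensitive decisions: minimum-expected-misclassification-cost
# thresholding of predicted probabilities, and the serial cost search under
# a false-positive-rate cap with stratified k-fold cross-validation.

#' Construct a misclassification cost model
#'
#' @param cost_fn cost of a false negative (missed active).
#' @param cost_fp cost of a false positive (default 1; correct
#'   classifications cost 0).
#' @return A [CostModel-class].
#' @examples
#' costThreshold(costModel(38))   # 1/39: the low threshold rescuing actives
#' @export
costModel <- function(cost_fn, cost_fp = 1) {
  new("CostModel", cost_fp = as.numeric(cost_fp), cost_fn = as.numeric(cost_fn))
}

#' Decision threshold of a cost model
#'
#' The expected cost of calling a compound active is \eqn{(1-p) c_{FP}}; of
#' calling it inactive, \eqn{p c_{FN}}. Minimum expected cost predicts active
#' iff \eqn{p > c_{FP} / (c_{FP} + c_{FN})}.
#'
#' @param cost a [CostModel-class].
#' @return The threshold in (0, 1\].
#' @export
costThreshold <- function(cost) cost@cost_fp / (cost@cost_fp + cost@cost_fn)

setMethod("show", "CostModel", function(object) {
  cat(sprintf("CostModel: cost_fp = %g, cost_fn = %g (threshold %.5g)\n",
              object@cost_fp, object@cost_fn, costThreshold(object)))
})

#' Minimum-expected-cost class prediction
#'
#' Predicts active iff \code{p_active * cost_fn > (1 - p_active) * cost_fp};
#' exact ties go to inactive.
#'
#' @param p_active numeric vector of probabilities in \[0, 1\].
#' @param cost a [CostModel-class].
#' @return Character vector over \{"active", "inactive"\}.
#' @export
costSensitivePredict <- function(p_active, cost) {
  stopifnot(all(p_active >= 0 & p_active <= 1))
  ifelse(p_active > costThreshold(cost), "active", "inactive")
}

#' Default serial cost schedule
#'
#' Geometric 1-2-5 ladder spanning 1 to 1e5, wide enough to cover both the
#' tens-scale costs a Naive Bayes needs and the 1e4-scale costs a Random
#' Forest needs on strongly imbalanced assays.
#' @return Increasing numeric vector.
#' @export
defaultCostSchedule <- function() {
  as.numeric(outer(c(1, 2, 5), 10^(0:4)))
}

#' Search the misclassification cost under a false-positive cap
#'
#' Cross-validated scores are computed once (they do not depend on the cost);
#' the cost ladder then moves the minimum-expected-cost threshold. Returns
#' the largest scheduled cost whose pooled k-fold CV false positive rate
#' stays at or below the cap, together with the full audit trace.
#'
#' @param x feature matrix or [DescriptorMatrix-class].
#' @param labels labels over \{"active", "inactive"\}.
#' @param train function(x, labels) returning a model scored by \code{score}.
#' @param fp_cap maximum tolerated CV false positive rate (default 0.20).
#' @param schedule strictly increasing positive cost sequence.
#' @param k CV folds (default 5).
#' @param score function(model, x) returning P(active).
#' @param seed fold-assignment seed.
#' @return List: \code{cost} (selected [CostModel-class]), \code{trace}
#'   (data.frame of cost, threshold, TPR, FPR, BCR), \code{cv} (the
#'   cross-validation scores object).
#' @export
tuneCost <- function(x, labels, train, fp_cap = 0.20,
                     schedule = defaultCostSchedule(), k = 5L,
                     score = predictProb, seed = 1L) {
  stopifnot(all(schedule > 0), !is.unsorted(schedule, strictly = TRUE))
  cv <- crossValidate(x, labels, k = k, train = train, score = score, seed = seed)
  lab <- as.character(labels)
  trace <- do.call(rbind, lapply(schedule, function(cfn) {
    cm <- costModel(cfn)
    pred <- costSensitivePredict(cv$scores, cm)
    met <- suppressWarnings(classificationMetrics(confusionCounts(lab, pred)))
    data.frame(cost = cfn, threshold = costThreshold(cm),
               TPR = met[["TPR"]], FPR = met[["FPR"]], BCR = met[["BCR"]])
  }))
  ok <- which(trace$FPR <= fp_cap)
  if (!length(ok)) {
    best <- trace[which.min(trace$FPR), ]
    stop(sprintf(paste("no scheduled cost satisfies FPR cap %.3g;",
                       "best infeasible point: cost %g (TPR %.3f, FPR %.3f)"),
                 fp_cap, best$cost, best$TPR, best$FPR))
  }
  sel <- max(ok)
  list(cost = costModel(trace$cost[sel]), trace = trace, cv = cv)
}
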