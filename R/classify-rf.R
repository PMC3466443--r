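# Random forest contract: a probability forest (fraction of trees voting
# active) behind the same predictProb() surface as the Naive Bayes model.
# The forest itself is fitted with ranger (100 trees, sqrt(m) features per
# split, Gini impurity, unlimited depth).

#' Train a random forest activity classifier
#'
#' @param x feature matrix or [DescriptorMatrix-class].
#' @param labels labels over \{"active", "inactive"\}, both present.
#' @param trees number of trees (default 100).
#' @param mtry features tried per split; default \code{floor(sqrt(ncol))}.
#' @param seed integer seed: same seed, same forest, same predictions.
#' @return A [RandomForestModel-class]; \code{predictProb} returns the
#'   fraction of trees voting active.
#' @export
trainRandomForest <- function(x, labels, trees = 100L, mtry = NULL, seed = 1L) {
  if (is(x, "DescriptorMatrix")) x <- x@values
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("training data must contain both classes")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  df <- as.data.frame(x)
  colnames(df) <- paste0("V", seq_len(ncol(df)))  # ranger-safe names
  df$.class <- factor(labels, levels = c("active", "inactive"))
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = trees, mtry = mtry, probability = TRUE,
    respect.unordered.factors = "order", num.threads = 1L,
    seed = as.integer(seed))
  new("RandomForestModel", fit = fit, columns = colnames(x))
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "RandomForestModel", function(model, x) {
  if (is(x, "DescriptorMatrix")) x <- x@values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, model@columns))
  if (!all(model@columns %in% colnames(x)))
    stop("descriptor columns do not match the model")
  df <- as.data.frame(x[, model@columns, drop = FALSE])
  colnames(df) <- paste0("V", seq_len(ncol(df)))
  p <- predict(model@fit, data = df, num.threads = 1L)$predictions
  unname(p[, "active"])
})

setMethod("show", "RandomForestModel", function(object) {
  cat(sprintf("RandomForestModel: %d trees over %d descriptors\n",
              object@fit$num.trees, length(object@columns)))
})

setMethod("show", "NaiveBayesModel", function(object) {
  cat(sprintf("NaiveBayesModel: priors %.4g/%.4g, %d binary + %d continuous descriptors\n",
              object@priors[["active"]], object@priors[["inactive"]],
              sum(object@binary), sum(!object@binary)))
})

#' Consensus virtual screen across models
#'
#' Scores a library with each trained model, applies the cost threshold, and
#' intersects the predicted-active id sets.
#'
#' @param models named list of trained models (anything with a
#'   [predictProb()] method).
#' @param x feature matrix or [DescriptorMatrix-class] with row ids.
#' @param cost a [CostModel-class] (default: equal costs, threshold 0.5).
#' @return List with \code{per_model} (named list of predicted-active id
#'   vectors) and \code{consensus} (their intersection, in library order).
#' @export
consensusScreen <- function(models, x, cost = costModel(1)) {
  if (is(x, "DescriptorMatrix")) x <- x@values
  stopifnot(length(models) >= 1L, !is.null(rownames(x)))
  perModel <- lapply(models, function(m) {
    p <- predictProb(m, x)
    rownames(x)[costSensitivePredict(p, cost) == "active"]
  })
  if (is.null(names(models))) names(perModel) <- paste0("model", seq_along(models))
  consensus <- Reduce(intersect, perModel)
  consensus <- rownames(x)[rownames(x) %in% consensus]  # library order
  list(per_model = perModel, consensus = consensus)
}
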