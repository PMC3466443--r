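# Model evaluation: confusion matrices, rate metrics and BCR, ROC/AUC,
# stratified k-fold cross-validation.

#' Confusion counts for a two-class problem
#'
#' "active" is the positive class: TP = active predicted active, FP =
#' inactive predicted active, TN = inactive predicted inactive, FN = active
#' predicted inactive.
#'
#' @param labels,predictions equal-length vectors over
#'   \{"active", "inactive"\}.
#' @return Named integer vector \code{c(TP, FP, TN, FN)}.
#' @export
confusionCounts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop("labels and predictions must have equal length")
  ok <- c("active", "inactive")
  if (!all(labels %in% ok) || !all(predictions %in% ok))
    stop("labels/predictions must be 'active' or 'inactive'")
  c(TP = sum(labels == "active" & predictions == "active"),
    FP = sum(labels == "inactive" & predictions == "active"),
    TN = sum(labels == "inactive" & predictions == "inactive"),
    FN = sum(labels == "active" & predictions == "inactive"))
}

#' Classification metrics from confusion counts
#'
#' TPR = TP/(TP+FN); FPR = FP/(FP+TN); sensitivity = TPR; specificity =
#' TN/(TN+FP); accuracy = (TP+TN)/total; BCR = (sensitivity+specificity)/2.
#' Rates over an empty class are returned as NaN with a warning, never as a
#' silent 0.
#'
#' @param cm named counts from [confusionCounts()].
#' @return Named numeric vector \code{TPR, FPR, sensitivity, specificity,
#'   accuracy, BCR}, all in \[0, 1\] (or NaN where undefined).
#' @export
classificationMetrics <- function(cm) {
  cm <- cm[c("TP", "FP", "TN", "FN")]
  if (anyNA(cm) || any(cm < 0)) stop("confusion counts must be non-negative TP/FP/TN/FN")
  pos <- cm[["TP"]] + cm[["FN"]]
  neg <- cm[["FP"]] + cm[["TN"]]
  if (pos == 0L) warning("no actual positives: TPR/sensitivity undefined (NaN)")
  if (neg == 0L) warning("no actual negatives: FPR/specificity undefined (NaN)")
  tpr <- if (pos > 0L) cm[["TP"]] / pos else NaN
  fpr <- if (neg > 0L) cm[["FP"]] / neg else NaN
  spec <- if (neg > 0L) cm[["TN"]] / neg else NaN
  acc <- (cm[["TP"]] + cm[["TN"]]) / sum(cm)
  c(TPR = tpr, FPR = fpr, sensitivity = tpr, specificity = spec,
    accuracy = acc, BCR = (tpr + spec) / 2)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds (predict active when score > t) and computes
#' the trapezoid area, which equals the Mann-Whitney pair statistic with ties
#' counted 1/2.
#'
#' @param labels vector over \{"active", "inactive"\}; both classes required.
#' @param scores real-valued scores, higher = more active.
#' @return List with \code{curve} (data.frame of FPR, TPR points) and
#'   \code{auc}.
#' @export
rocAuc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  pos <- labels == "active"
  if (!any(pos) || all(pos)) stop("ROC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  y <- pos[ord]; s <- scores[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  # keep only the last point of each tied-score block
  keep <- c(s[-length(s)] != s[-1], TRUE)
  tpr <- c(0, tp[keep] / sum(pos))
  fpr <- c(0, fp[keep] / sum(!pos))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = data.frame(FPR = fpr, TPR = tpr), auc = auc)
}

#' Stratified k-fold cross-validation
#'
#' Assigns every record to exactly one of k folds, stratified by class;
#' trains the pipeline on the complement and scores the held-out fold. The
#' pooled confusion matrix is the sum over folds (pooled total = n).
#'
#' @param x matrix (or [DescriptorMatrix-class]) of features.
#' @param labels class labels over \{"active", "inactive"\}.
#' @param k number of folds (default 5); every class must have >= k records.
#' @param train function(x, labels) returning a model.
#' @param score function(model, x) returning P(active); defaults to
#'   [predictProb()].
#' @param threshold decision threshold on P(active) (predict active when
#'   strictly above). Default 0.5.
#' @param seed integer seed for the fold assignment.
#' @return List: \code{fold} (integer assignment), \code{scores} (out-of-fold
#'   P(active)), \code{pooled} (confusion counts), \code{metrics} (pooled),
#'   \code{per_fold} (list of per-fold metric vectors).
#' @export
crossValidate <- function(x, labels, k = 5L, train, score = predictProb,
                          threshold = 0.5, seed = 1L) {
  if (is(x, "DescriptorMatrix")) x <- x@values
  stopifnot(nrow(x) == length(labels))
  sizes <- table(labels)
  if (any(sizes < k)) stop("every class needs at least k records for ", k, "-fold CV")
  rng <- .seededRNG(seed)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    perm <- .rngSample(rng, idx, length(idx))
    fold[perm] <- rep_len(seq_len(k), length(idx))
  }
  scores <- numeric(length(labels))
  perFold <- vector("list", k)
  pooled <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (f in seq_len(k)) {
    te <- fold == f
    model <- train(x[!te, , drop = FALSE], labels[!te])
    sc <- score(model, x[te, , drop = FALSE])
    scores[te] <- sc
    pred <- ifelse(sc > threshold, "active", "inactive")
    cm <- confusionCounts(labels[te], pred)
    pooled <- pooled + cm
    perFold[[f]] <- suppressWarnings(classificationMetrics(cm))
  }
  list(fold = fold, scores = scores, pooled = pooled,
       metrics = suppressWarnings(classificationMetrics(pooled)),
       per_fold = perFold)
}
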