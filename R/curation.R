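# Assay curation: activity-score banding, counter-screen filtering, modeling
# set assembly, stratified train/test splitting.
#
# Banding follows the PubChem activity-score convention used for the miR-21
# screen: scores 40-100 are active, 0 inactive, 1-39 inconclusive.

#' Band a PubChem-style activity score into a class
#'
#' @param score integer vector of activity scores in \[0, 100\].
#' @return Character vector over \{"active", "inactive", "inconclusive"\}:
#'   40-100 active (inclusive), 0 inactive, 1-39 inconclusive.
#' @examples
#' bandActivity(c(0, 1, 39, 40, 100))
#' @export
bandActivity <- function(score) {
  score <- as.integer(score)
  if (anyNA(score) || any(score < 0L | score > 100L))
    stop("activity scores must be integers in [0, 100]")
  ifelse(score >= 40L, "active", ifelse(score == 0L, "inactive", "inconclusive"))
}

#' Assemble an assay dataset
#'
#' @param ids compound ids (unique).
#' @param score integer activity scores in \[0, 100\].
#' @param counterscreen_hit logical flags (default all FALSE).
#' @return A data.frame with columns \code{id}, \code{score}, \code{class},
#'   \code{counterscreen_hit}, carrying per-class counts as
#'   \code{attr(, "counts")}.
#' @export
assayDataset <- function(ids, score, counterscreen_hit = FALSE) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate compound ids in assay dataset")
  d <- data.frame(id = ids, score = as.integer(score),
                  class = bandActivity(score),
                  counterscreen_hit = rep_len(as.logical(counterscreen_hit), length(ids)),
                  stringsAsFactors = FALSE)
  attr(d, "counts") <- table(factor(d$class, c("active", "inactive", "inconclusive")))
  d
}

#' Remove counter-screen artifact hits from the active class
#'
#' Active records whose id appears in the flagged set are dropped entirely
#' (not relabelled); inactive and inconclusive records are untouched. The
#' removal count is reported and attached as \code{attr(, "removed")}.
#'
#' @param dataset a banded assay data.frame from [assayDataset()].
#' @param flagged character vector of counter-screen hit ids.
#' @return The filtered dataset.
#' @examples
#' d <- assayDataset(c("a", "b", "c"), c(80, 50, 0))
#' counterscreenFilter(d, "a")   # 1 active removed
#' @export
counterscreenFilter <- function(dataset, flagged) {
  flagged <- as.character(flagged)
  drop <- dataset$class == "active" & dataset$id %in% flagged
  if (sum(dataset$class == "active") > 0L && all(dataset$class != "active" | drop))
    warning("all active records were counter-screen hits; no actives remain")
  out <- dataset[!drop, , drop = FALSE]
  rownames(out) <- NULL
  message(sum(drop), " active record(s) removed as counter-screen hits")
  attr(out, "removed") <- sum(drop)
  attr(out, "counts") <- table(factor(out$class, c("active", "inactive", "inconclusive")))
  out
}

#' Reduce a curated dataset to the modeling classes
#'
#' Keeps active and inactive records; inconclusive records are dropped with a
#' logged count. Errors if either modeling class is empty.
#'
#' @param dataset a banded (and typically counter-screen filtered) dataset.
#' @return Data.frame of active/inactive records.
#' @export
makeModelingSet <- function(dataset) {
  keep <- dataset$class %in% c("active", "inactive")
  message(sum(!keep), " inconclusive record(s) excluded from modeling")
  out <- dataset[keep, , drop = FALSE]
  if (!any(out$class == "active")) stop("no active records: cannot train")
  if (!any(out$class == "inactive")) stop("no inactive records: cannot train")
  rownames(out) <- NULL
  out
}

#' Stratified train/test split
#'
#' Splits by class so the test set holds \code{round(fraction * n_class)}
#' records of each class; reproducible under a fixed seed.
#'
#' @param dataset modeling data.frame with a \code{class} column.
#' @param test_fraction test proportion (default 0.2).
#' @param seed integer RNG seed.
#' @return List with \code{train} and \code{test} data.frames (a partition of
#'   the input).
#' @export
splitTrainTest <- function(dataset, test_fraction = 0.2, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  cls <- unique(dataset$class)
  sizes <- table(dataset$class)
  if (any(sizes < 5L))
    stop("each class needs at least 5 records to split (got ",
         paste(names(sizes), sizes, collapse = ", "), ")")
  rng <- .seededRNG(seed)
  testIdx <- integer()
  for (cl in sort(cls)) {
    idx <- which(dataset$class == cl)
    k <- round(test_fraction * length(idx))
    testIdx <- c(testIdx, .rngSample(rng, idx, k))
  }
  test <- dataset[sort(testIdx), , drop = FALSE]
  train <- dataset[setdiff(seq_len(nrow(dataset)), testIdx), , drop = FALSE]
  rownames(test) <- NULL; rownames(train) <- NULL
  list(train = train, test = test)
}

# Local RNG helpers: every stochastic operation takes an explicit seed and
# restores the caller's RNG state.
.seededRNG <- function(seed) {
  env <- new.env()
  env$seed <- as.integer(seed)
  env
}

.withSeed <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    rng$seed <- sample.int(.Machine$integer.max, 1L)
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(rng$seed)
  expr
}

.rngSample <- function(rng, x, size) .withSeed(rng, sample(x, size))
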