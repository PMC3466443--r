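# From-scratch two-class Naive Bayes for mixed binary/continuous descriptor
# matrices: Laplace-smoothed Bernoulli likelihoods for fingerprint bits,
# Gaussian likelihoods with a floored standard deviation for continuous
# columns. Posterior computed in log space and normalized.

#' Train a Naive Bayes classifier
#'
#' @param x numeric matrix or [DescriptorMatrix-class]; binary columns get
#'   Bernoulli likelihoods, continuous columns Gaussian likelihoods.
#' @param labels vector over \{"active", "inactive"\}, both classes present.
#' @param binary logical flags per column; inferred from a DescriptorMatrix,
#'   otherwise defaults to "all values in \{0,1\}".
#' @param alpha Laplace smoothing count (default 1).
#' @param sigma_floor lower bound on class-conditional standard deviations.
#' @return A [NaiveBayesModel-class].
#' @examples
#' x <- cbind(bit = c(1, 1, 0, 0))
#' m <- trainNaiveBayes(x, c("active", "active", "inactive", "inactive"))
#' m@p1["active", "bit"]   # (2 + 1) / (2 + 2) = 0.75
#' @export
trainNaiveBayes <- function(x, labels, binary = NULL, alpha = 1,
                            sigma_floor = 1e-9) {
  if (is(x, "DescriptorMatrix")) { binary <- x@binary; x <- x@values }
  stopifnot(nrow(x) == length(labels))
  labels <- as.character(labels)
  if (!all(c("active", "inactive") %in% labels))
    stop("training data must contain both classes")
  if (is.null(binary)) binary <- apply(x, 2, function(v) all(v %in% c(0, 1)))
  cls <- c("active", "inactive")
  nByClass <- vapply(cls, function(cl) sum(labels == cl), numeric(1))
  priors <- nByClass / sum(nByClass)
  bcols <- which(binary); ccols <- which(!binary)
  p1 <- matrix(NA_real_, 2, length(bcols),
               dimnames = list(cls, colnames(x)[bcols]))
  mu <- sigma <- matrix(NA_real_, 2, length(ccols),
                        dimnames = list(cls, colnames(x)[ccols]))
  for (ci in 1:2) {
    rows <- labels == cls[ci]
    if (length(bcols))
      p1[ci, ] <- (colSums(x[rows, bcols, drop = FALSE]) + alpha) /
        (sum(rows) + 2 * alpha)
    if (length(ccols)) {
      xc <- x[rows, ccols, drop = FALSE]
      mu[ci, ] <- colMeans(xc)
      s <- apply(xc, 2, sd)
      s[is.na(s)] <- 0
      sigma[ci, ] <- pmax(s, sigma_floor)
    }
  }
  new("NaiveBayesModel", priors = setNames(priors, cls), p1 = p1, mu = mu,
      sigma = sigma, columns = colnames(x), binary = setNames(binary, colnames(x)),
      alpha = alpha)
}

#' Posterior probability of activity under a Naive Bayes model
#'
#' Computed in log space; the two class posteriors are normalized to sum
#' to 1. Equivalent to the direct product of per-descriptor probability
#' ratios.
#'
#' @param model a [NaiveBayesModel-class].
#' @param x numeric matrix (or [DescriptorMatrix-class]) with the model's
#'   training columns.
#' @return Numeric vector of P(active | x).
#' @export
nbPosterior <- function(model, x) {
  if (is(x, "DescriptorMatrix")) x <- x@values
  if (is.null(dim(x))) x <- matrix(x, nrow = 1, dimnames = list(NULL, model@columns))
  if (!all(model@columns %in% colnames(x)))
    stop("descriptor columns do not match the model")
  x <- x[, model@columns, drop = FALSE]
  logpost <- matrix(rep(log(model@priors), each = nrow(x)), nrow(x), 2)
  bcols <- names(model@binary)[model@binary]
  ccols <- names(model@binary)[!model@binary]
  for (ci in 1:2) {
    if (length(bcols)) {
      xb <- x[, bcols, drop = FALSE]
      p <- model@p1[ci, ]
      logpost[, ci] <- logpost[, ci] +
        xb %*% log(p) + (1 - xb) %*% log(1 - p)
    }
    if (length(ccols)) {
      xc <- x[, ccols, drop = FALSE]
      mu <- model@mu[ci, ]; s <- model@sigma[ci, ]
      ll <- -0.5 * sweep(sweep(xc, 2, mu), 2, s, "/")^2
      ll <- sweep(ll, 2, log(s) + 0.5 * log(2 * pi))
      logpost[, ci] <- logpost[, ci] + rowSums(ll)
    }
  }
  m <- pmax(logpost[, 1], logpost[, 2])
  ea <- exp(logpost[, 1] - m); ei <- exp(logpost[, 2] - m)
  unname(ea / (ea + ei))
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "NaiveBayesModel", function(model, x) nbPosterior(model, x))

#' Serialize / restore a Naive Bayes model as versioned JSON
#'
#' @param model a [NaiveBayesModel-class].
#' @param path JSON file path.
#' @return \code{writeNBModel}: invisibly the path; \code{readNBModel}: the
#'   model.
#' @export
writeNBModel <- function(model, path) {
  jsonlite::write_json(list(
    format = "ScaffoldScreen-NB", version = 1L,
    priors = as.list(model@priors), alpha = model@alpha,
    columns = model@columns, binary = as.logical(model@binary),
    p1 = list(active = unname(model@p1["active", ]), inactive = unname(model@p1["inactive", ])),
    mu = list(active = unname(model@mu["active", ]), inactive = unname(model@mu["inactive", ])),
    sigma = list(active = unname(model@sigma["active", ]), inactive = unname(model@sigma["inactive", ]))
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNBModel
#' @export
readNBModel <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "ScaffoldScreen-NB")) stop("not a ScaffoldScreen NB model file")
  cols <- j$columns
  binary <- setNames(j$binary, cols)
  bcols <- cols[binary]; ccols <- cols[!binary]
  new("NaiveBayesModel",
      priors = unlist(j$priors)[c("active", "inactive")],
      p1 = rbind(active = setNames(j$p1$active, bcols),
                 inactive = setNames(j$p1$inactive, bcols)),
      mu = rbind(active = setNames(j$mu$active, ccols),
                 inactive = setNames(j$mu$inactive, ccols)),
      sigma = rbind(active = setNames(j$sigma$active, ccols),
                    inactive = setNames(j$sigma$inactive, ccols)),
      columns = cols, binary = binary, alpha = j$alpha)
}
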