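#' @name accessors
#' @title Accessors for ScaffoldScreen classes
#' @param x object.
#' @param object object (for \code{show}).
#' @param ... unused.
#' @return The slot contents (see the individual class pages).
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname accessors
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname accessors
#' @export
setGeneric("molName", function(x) standardGeneric("molName"))

#' @rdname accessors
#' @export
setGeneric("heavyAtomCount", function(x) standardGeneric("heavyAtomCount"))

#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname accessors
#' @export
setGeneric("molecules", function(x) standardGeneric("molecules"))

#' @rdname accessors
#' @export
setGeneric("compoundProperties", function(x) standardGeneric("compoundProperties"))

#' @rdname accessors
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' @rdname accessors
#' @export
setGeneric("retainedColumns", function(x) standardGeneric("retainedColumns"))

#' @rdname accessors
#' @export
setGeneric("binaryColumns", function(x) standardGeneric("binaryColumns"))

#' Predict the probability of activity
#'
#' @param model a trained [NaiveBayesModel-class] or [RandomForestModel-class].
#' @param x a [DescriptorMatrix-class] or numeric matrix whose columns match
#'   the model's training columns.
#' @return Numeric vector of \eqn{P(\mathrm{active} \mid x)} in \[0, 1\].
#' @export
setGeneric("predictProb", function(model, x) standardGeneric("predictProb"))
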