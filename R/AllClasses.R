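#' Labelled 2D chemical graph
#'
#' Heavy-atom molecular graph: atoms carry an element symbol, a formal
#' charge and an aromatic flag; bonds carry an order (1, 2, 3, or 4 for
#' aromatic). Hydrogens are implicit and never appear as graph atoms. The
#' optional \code{hcount} column pins an explicit hydrogen count (as written
#' in a SMILES bracket atom); \code{NA} means "derive from standard valence".
#'
#' @slot atoms data.frame with columns \code{element} (character),
#'   \code{charge} (integer), \code{aromatic} (logical), \code{hcount}
#'   (integer, may be \code{NA}).
#' @slot bonds data.frame with columns \code{i}, \code{j} (1-based atom
#'   indices, \code{i < j}) and \code{order} (integer; 4 = aromatic).
#' @slot name single character identifier (may be \code{""}).
#'
#' @seealso [parseSmiles()], [molToSmiles()], [isSubstructure()], [mcs()]
#' @export
setClass("MolecularGraph",
  representation(atoms = "data.frame", bonds = "data.frame", name = "character"))

setValidity("MolecularGraph", function(object) {
  a <- object@atoms; b <- object@bonds
  msgs <- character()
  need_a <- c("element", "charge", "aromatic", "hcount")
  need_b <- c("i", "j", "order")
  if (!all(need_a %in% names(a))) return("atoms must have columns element, charge, aromatic, hcount")
  if (!all(need_b %in% names(b))) return("bonds must have columns i, j, order")
  if (length(object@name) != 1L) msgs <- c(msgs, "name must be a single string")
  if (!all(a$element %in% .ELEMENTS$symbol))
    msgs <- c(msgs, paste("unsupported element(s):",
                          paste(setdiff(unique(a$element), .ELEMENTS$symbol), collapse = ", ")))
  n <- nrow(a)
  if (nrow(b)) {
    if (any(b$i < 1L | b$i > n | b$j < 1L | b$j > n))
      msgs <- c(msgs, "bond endpoints must index valid atoms")
    else {
      if (any(b$i == b$j)) msgs <- c(msgs, "self-loop bonds are not allowed")
      key <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
      if (anyDuplicated(key)) msgs <- c(msgs, "at most one bond per atom pair")
    }
    if (!all(b$order %in% 1:4)) msgs <- c(msgs, "bond order must be 1, 2, 3 or 4 (aromatic)")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MolecularGraph
#'
#' @param atoms data.frame with columns \code{element}, and optionally
#'   \code{charge}, \code{aromatic}, \code{hcount} (defaults 0, FALSE, NA).
#' @param bonds data.frame with columns \code{i}, \code{j}, \code{order}
#'   (1-based atom indices; order 4 = aromatic). May be empty or missing.
#' @param name compound identifier.
#' @return A [MolecularGraph-class] object.
#' @examples
#' mg <- MolecularGraph(
#'   atoms = data.frame(element = c("C", "C", "O")),
#'   bonds = data.frame(i = c(1, 2), j = c(2, 3), order = 1))
#' heavyAtomCount(mg)
#' @export
MolecularGraph <- function(atoms, bonds = NULL, name = "") {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$charge)) atoms$charge <- rep(0L, nrow(atoms))
  if (is.null(atoms$aromatic)) atoms$aromatic <- rep(FALSE, nrow(atoms))
  if (is.null(atoms$hcount)) atoms$hcount <- rep(NA_integer_, nrow(atoms))
  atoms <- data.frame(element = as.character(atoms$element),
                      charge = as.integer(atoms$charge),
                      aromatic = as.logical(atoms$aromatic),
                      hcount = as.integer(atoms$hcount),
                      stringsAsFactors = FALSE)
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- data.frame(i = integer(), j = integer(), order = integer())
  } else {
    bonds <- as.data.frame(bonds)
    bonds <- data.frame(i = as.integer(pmin(bonds$i, bonds$j)),
                        j = as.integer(pmax(bonds$i, bonds$j)),
                        order = as.integer(bonds$order))
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  new("MolecularGraph", atoms = atoms, bonds = bonds, name = as.character(name))
}

#' Ordered collection of compounds
#'
#' An id-indexed, order-preserving list of [MolecularGraph-class] objects
#' with an optional per-compound property table (e.g. SDF data fields,
#' preserved verbatim as character).
#'
#' @slot ids character vector of unique compound ids.
#' @slot mols list of MolecularGraph objects, parallel to \code{ids}.
#' @slot properties data.frame of per-compound properties (0 columns allowed),
#'   with one row per compound.
#' @export
setClass("CompoundLibrary",
  representation(ids = "character", mols = "list", properties = "data.frame"))

setValidity("CompoundLibrary", function(object) {
  msgs <- character()
  if (length(object@ids) != length(object@mols))
    msgs <- c(msgs, "ids and mols must have equal length")
  if (anyDuplicated(object@ids)) msgs <- c(msgs, "compound ids must be unique")
  if (!all(vapply(object@mols, is, logical(1), class2 = "MolecularGraph")))
    msgs <- c(msgs, "mols must all be MolecularGraph objects")
  if (nrow(object@properties) != length(object@ids))
    msgs <- c(msgs, "properties must have one row per compound")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CompoundLibrary
#'
#' @param mols list of [MolecularGraph-class] objects.
#' @param ids compound ids; defaults to molecule names, falling back to the
#'   1-based ordinal where empty. Duplicated ids are made unique with a warning.
#' @param properties optional data.frame of per-compound properties.
#' @return A [CompoundLibrary-class].
#' @examples
#' lib <- CompoundLibrary(list(parseSmiles("CCO"), parseSmiles("c1ccccc1")),
#'                        ids = c("ethanol", "benzene"))
#' length(lib)
#' @export
CompoundLibrary <- function(mols, ids = NULL, properties = NULL) {
  mols <- as.list(mols)
  if (is.null(ids)) {
    ids <- vapply(mols, function(m) m@name, character(1))
    ids[!nzchar(ids)] <- as.character(seq_along(mols))[!nzchar(ids)]
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    warning("duplicated compound ids made unique")
    ids <- make.unique(ids)
  }
  if (is.null(properties)) {
    properties <- data.frame(row.names = seq_along(mols))
  } else {
    properties <- as.data.frame(properties)
    rownames(properties) <- NULL
  }
  new("CompoundLibrary", ids = ids, mols = mols, properties = properties)
}

#' Per-compound 2D descriptor matrix
#'
#' Holds the 179-column descriptor block (147 pharmacophore-pair fingerprint
#' bits, 24 Burden eigenvalues, 8 whole-molecule properties), the binary /
#' continuous column typing, and the retained-column mask produced by
#' constant-bit filtering.
#'
#' @slot values numeric matrix, one row per compound (rownames = ids).
#' @slot binary logical vector flagging binary (fingerprint-bit) columns.
#' @slot retained logical mask over the original columns; filtered matrices
#'   keep the mask so provenance survives.
#' @slot metadata list of generation parameters (scheme versions etc.).
#' @export
setClass("DescriptorMatrix",
  representation(values = "matrix", binary = "logical", retained = "logical",
                 metadata = "list"))

setValidity("DescriptorMatrix", function(object) {
  msgs <- character()
  if (ncol(object@values) != length(object@binary))
    msgs <- c(msgs, "binary flags must match column count")
  if (sum(object@retained) != ncol(object@values))
    msgs <- c(msgs, "retained mask must select exactly the present columns")
  if (length(msgs)) msgs else TRUE
})

#' Cost-sensitive two-class Naive Bayes model
#'
#' Laplace-smoothed Bernoulli likelihoods for binary descriptor columns and
#' Gaussian likelihoods (variance floored) for continuous columns; class
#' priors from training frequencies.
#'
#' @slot priors named numeric, \code{c(active=, inactive=)}, summing to 1.
#' @slot p1 matrix (2 x binary columns) of P(bit = 1 | class).
#' @slot mu,sigma matrices (2 x continuous columns) of class-conditional
#'   Gaussian parameters.
#' @slot columns character, training column names in order.
#' @slot binary logical flags over \code{columns}.
#' @slot alpha Laplace smoothing count.
#' @export
setClass("NaiveBayesModel",
  representation(priors = "numeric", p1 = "matrix", mu = "matrix",
                 sigma = "matrix", columns = "character", binary = "logical",
                 alpha = "numeric"))

#' Random forest classifier wrapper
#'
#' Thin wrapper around a \pkg{ranger} probability forest so that forests and
#' Naive Bayes models share the [predictProb()] / [consensusScreen()] surface.
#'
#' @slot fit the fitted \code{ranger} object.
#' @slot columns training column names in order.
#' @export
setClass("RandomForestModel", representation(fit = "ANY", columns = "character"))

#' Misclassification cost model
#'
#' Costs for the two error types (correct classifications cost 0). The
#' minimum-expected-cost rule predicts active when
#' \eqn{p \cdot c_{FN} > (1-p) \cdot c_{FP}}, i.e. above the threshold
#' \eqn{t = c_{FP} / (c_{FP} + c_{FN})}; ties go to inactive.
#'
#' @slot cost_fp,cost_fn non-negative reals.
#' @export
setClass("CostModel", representation(cost_fp = "numeric", cost_fn = "numeric"))

setValidity("CostModel", function(object) {
  if (object@cost_fp < 0 || object@cost_fn < 0) "costs must be non-negative"
  else if (object@cost_fp + object@cost_fn == 0) "at least one cost must be positive"
  else TRUE
})

#' Scaffold cluster hierarchy
#'
#' Result of LibMCS-style greedy agglomeration: a forest of clusters, each
#' with a level (1 = leaves), a representative scaffold graph and member ids.
#'
#' @slot clusters list of cluster records (list with \code{level},
#'   \code{scaffold}, \code{members}, \code{children}).
#' @slot levels number of levels built.
#' @slot min_mcs_atoms the merge threshold (heavy atoms) used.
#' @export
setClass("ScaffoldHierarchy",
  representation(clusters = "list", levels = "integer", min_mcs_atoms = "integer"))
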