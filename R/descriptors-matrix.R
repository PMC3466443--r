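# Library featurization into the 179-column descriptor matrix, constant-bit
# filtering, and CSV round-trip with a JSON sidecar.

#' Fixed names of all 179 descriptor columns
#'
#' 147 pharmacophore-pair fingerprint bits, 24 Burden eigenvalues, 8
#' whole-molecule properties, in that order.
#' @return Character vector of length 179.
#' @export
descriptorColumnNames <- function() {
  c(fingerprintColumnNames(),
    paste0("BN_", rep(c("EN", "Q", "LP"), each = 8), "_",
           rep(c(paste0("lo", 1:4), paste0("hi", 1:4)), 3)),
    .PROPERTY_NAMES)
}

#' Full 179-value descriptor vector for one molecule
#'
#' @param mol a connected, sanitized [MolecularGraph-class].
#' @return Named numeric vector of length 179.
#' @export
descriptorVector <- function(mol) {
  c(pharmacophoreFingerprint(mol), burdenDescriptors(mol), propertyDescriptors(mol))
}

#' @rdname accessors
#' @export
setMethod("descriptorValues", "DescriptorMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("retainedColumns", "DescriptorMatrix", function(x) x@retained)

#' @rdname accessors
#' @export
setMethod("binaryColumns", "DescriptorMatrix", function(x) x@binary)

setMethod("show", "DescriptorMatrix", function(object) {
  cat(sprintf("DescriptorMatrix: %d compounds x %d descriptors (%d binary), %d/%d columns retained\n",
              nrow(object@values), ncol(object@values), sum(object@binary),
              sum(object@retained), length(object@retained)))
})

#' Featurize a compound library
#'
#' Computes the 179-column descriptor block for every compound (in input
#' order). Multi-fragment molecules are reduced to their largest fragment
#' first; compounds whose descriptor computation fails are dropped with a
#' message naming the ids.
#'
#' @param library a [CompoundLibrary-class].
#' @return A [DescriptorMatrix-class] with one row per (retained) compound.
#' @export
featurizeLibrary <- function(library) {
  stopifnot(length(library) > 0L)
  library <- standardizeLibrary(library)
  cols <- descriptorColumnNames()
  rows <- lapply(seq_along(library@ids), function(k)
    tryCatch(descriptorVector(library@mols[[k]]), error = function(e) NULL))
  failed <- vapply(rows, is.null, logical(1))
  if (any(failed))
    message("dropped ", sum(failed), " compound(s) failing featurization: ",
            paste(head(library@ids[failed], 10), collapse = ", "))
  values <- do.call(rbind, rows[!failed])
  rownames(values) <- library@ids[!failed]
  colnames(values) <- cols
  binary <- setNames(c(rep(TRUE, 147L), rep(FALSE, 32L)), cols)
  new("DescriptorMatrix", values = values, binary = binary,
      retained = setNames(rep(TRUE, length(cols)), cols),
      metadata = list(logp_scheme = "coarseXLogP-1", charge_scheme = "PEOE-6iter",
                      fingerprint = "6class-7bin-v1"))
}

#' Build a DescriptorMatrix from a plain matrix
#'
#' Mostly useful for simulated descriptor matrices and tests.
#'
#' @param values numeric matrix with column names and row ids.
#' @param binary logical flags per column (default: 0/1-valued columns).
#' @param metadata optional list.
#' @return A [DescriptorMatrix-class].
#' @export
descriptorMatrix <- function(values, binary = NULL, metadata = list()) {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("X", seq_len(ncol(values)))
  if (is.null(binary))
    binary <- apply(values, 2, function(v) all(v %in% c(0, 1)))
  new("DescriptorMatrix", values = values,
      binary = setNames(as.logical(binary), colnames(values)),
      retained = setNames(rep(TRUE, ncol(values)), colnames(values)),
      metadata = metadata)
}

#' Remove constant binary descriptor columns
#'
#' Drops fingerprint-bit columns that take a single value (all 0 or all 1)
#' across the dataset; continuous columns are never removed by this rule.
#' The retained mask (over the original columns) records the filtering, so
#' the operation is idempotent and auditable.
#'
#' @param x a [DescriptorMatrix-class] with at least one row.
#' @return A filtered [DescriptorMatrix-class].
#' @export
filterConstantBits <- function(x) {
  stopifnot(is(x, "DescriptorMatrix"), nrow(x@values) >= 1L)
  v <- x@values
  constant <- x@binary & apply(v, 2, function(col) length(unique(col)) == 1L)
  if (!any(constant)) return(x)
  keep <- !constant
  retained <- x@retained
  retained[colnames(v)[constant]] <- FALSE
  new("DescriptorMatrix", values = v[, keep, drop = FALSE],
      binary = x@binary[keep], retained = retained, metadata = x@metadata)
}

#' Write / read a descriptor matrix as CSV plus JSON sidecar
#'
#' The CSV holds the compound id as its first column; the sidecar
#' (\code{<path>.json}) records the column typing, the retained mask and the
#' generation metadata so a round trip is lossless.
#'
#' @param x a [DescriptorMatrix-class].
#' @param path CSV path.
#' @return \code{writeDescriptorMatrix}: invisibly, the path;
#'   \code{readDescriptorMatrix}: a [DescriptorMatrix-class].
#' @export
writeDescriptorMatrix <- function(x, path) {
  df <- data.frame(compound_id = rownames(x@values), x@values,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(binary = as.list(setNames(as.logical(x@binary), names(x@binary))),
         retained = as.list(setNames(as.logical(x@retained), names(x@retained))),
         metadata = x@metadata),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeDescriptorMatrix
#' @export
readDescriptorMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  side <- jsonlite::read_json(paste0(path, ".json"))
  new("DescriptorMatrix", values = values,
      binary = setNames(unlist(side$binary), names(side$binary)),
      retained = setNames(unlist(side$retained), names(side$retained)),
      metadata = side$metadata)
}
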