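# SDF (MDL V2000) input / output. Reading is delegated to ChemmineR's SDF
# parser; formal charges are recovered from the raw `M  CHG` lines, which
# ChemmineR's atom block drops. V3000 records are rejected: the format
# targeted here is the classic V2000 dialect of PubChem exports.

#' Read an SDF file into a CompoundLibrary
#'
#' Every parsable V2000 record yields one compound; records that fail
#' sanitization are skipped and the skip count reported. Data fields are
#' preserved verbatim as character columns of the property table. Compound
#' ids come from the record title line, falling back to the 1-based record
#' ordinal; duplicated ids are made unique.
#'
#' @param path SDF file path.
#' @param perceiveAromaticity perceive aromaticity of kekulized rings in
#'   addition to honouring explicit order-4 bonds. Default TRUE.
#' @return A [CompoundLibrary-class]. The number of skipped records is
#'   attached as \code{attr(, "skipped")}.
#' @export
readSDF <- function(path, perceiveAromaticity = TRUE) {
  if (!file.exists(path)) stop("cannot read SDF file: ", path)
  raw <- ChemmineR::read.SDFstr(path)
  reclist <- as(raw, "list")
  if (any(vapply(reclist, function(r) any(grepl("V3000", r, fixed = TRUE)), logical(1))))
    stop("V3000 SDF records are not supported; supply a V2000 file")
  mols <- list(); ids <- character(); props <- list(); skipped <- 0L
  for (k in seq_along(reclist)) {
    rec <- tryCatch(.sdfRecordToMol(reclist[[k]], perceiveAromaticity),
                    error = function(e) NULL)
    if (is.null(rec)) { skipped <- skipped + 1L; next }
    id <- rec$id
    if (!nzchar(id)) id <- as.character(k)
    rec$mol@name <- id
    mols[[length(mols) + 1L]] <- rec$mol
    ids <- c(ids, id)
    props[[length(props) + 1L]] <- rec$props
  }
  if (skipped) message(skipped, " SDF record(s) skipped (failed to parse)")
  if (!length(mols)) stop("no parsable records in ", path)
  allKeys <- unique(unlist(lapply(props, names)))
  ptab <- as.data.frame(
    setNames(lapply(allKeys, function(key) vapply(props, function(p)
      if (key %in% names(p)) p[[key]] else NA_character_, character(1))), allKeys),
    optional = TRUE)
  if (!length(allKeys)) ptab <- data.frame(row.names = seq_along(mols))
  lib <- CompoundLibrary(mols, ids = ids, properties = ptab)
  attr(lib, "skipped") <- skipped
  lib
}

# one raw V2000 record (character vector of lines) -> MolecularGraph + fields
.sdfRecordToMol <- function(lines, perceiveAromaticity) {
  sdfset <- as(new("SDFstr", a = list(lines)), "SDFset")
  if (!ChemmineR::validSDF(sdfset)) stop("invalid SDF record")
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_.*$", "", rownames(ab))
  if (!all(element %in% .ELEMENTS$symbol)) stop("unsupported element in record")
  natoms <- nrow(ab)
  charge <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1]])
    cnt <- f[1]
    for (p in seq_len(cnt)) charge[f[2 * p]] <- f[2 * p + 1]
  }
  if (NROW(bb)) {
    bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                        order = as.integer(bb[, 3]))
    if (!all(bonds$order %in% 1:4)) stop("unsupported bond type")
  } else bonds <- NULL
  arom <- logical(natoms)
  if (!is.null(bonds) && any(bonds$order == 4L))
    arom[unique(c(bonds$i[bonds$order == 4L], bonds$j[bonds$order == 4L]))] <- TRUE
  mol <- MolecularGraph(
    data.frame(element = element, charge = charge, aromatic = arom,
               hcount = NA_integer_, stringsAsFactors = FALSE),
    bonds)
  validObject(mol)
  if (perceiveAromaticity) mol <- .perceiveAromaticity(mol)
  db <- ChemmineR::datablock(sdf)
  fields <- if (length(db)) as.list(vapply(db, as.character, character(1))) else list()
  list(mol = mol, id = trimws(lines[1]), props = fields)
}

#' Write a CompoundLibrary as an SDF (V2000) file
#'
#' Atoms are written with zero coordinates (the pipeline is 2D topological);
#' aromatic bonds as bond type 4; formal charges as \code{M  CHG} lines;
#' property columns as data fields.
#'
#' @param library a [CompoundLibrary-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeSDF <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  props <- library@properties
  for (k in seq_along(library@ids)) {
    mol <- library@mols[[k]]
    a <- mol@atoms; b <- mol@bonds
    lines <- c(library@ids[k], "  ScaffoldScreen", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(a), nrow(b)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, a$element))
    if (nrow(b))
      lines <- c(lines, sprintf("%3d%3d%3d  0", b$i, b$j, b$order))
    chg <- which(a$charge != 0L)
    while (length(chg)) {
      grp <- head(chg, 8L); chg <- chg[-seq_along(grp)]
      lines <- c(lines, paste0("M  CHG", sprintf("%3d", length(grp)),
                               paste0(sprintf("%4d%4d", grp, a$charge[grp]), collapse = "")))
    }
    lines <- c(lines, "M  END")
    for (key in names(props)) {
      val <- props[k, key]
      if (!is.na(val))
        lines <- c(lines, paste0("> <", key, ">"), as.character(val), "")
    }
    lines <- c(lines, "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}
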