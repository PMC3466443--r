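# Pharmacophore atom typing and the 147-bit pharmacophore-pair fingerprint.
#
# Six feature classes x binned topological distance. The published PowerMV
# atom-typing rules are not public at bit level; this implementation fixes a
# documented 6-class / 7-bin scheme that reproduces the descriptor *counts*
# (21 unordered class pairs x 7 shortest-path bins = 147 bits). Bin edges:
# path lengths 1..6 each their own bin, >= 7 pooled.

.PHARM_CLASSES <- c("donor", "acceptor", "posIonizable", "negIonizable",
                    "hydrophobe", "aromatic")

#' Assign pharmacophore feature classes to atoms
#'
#' Rules (2D, heavy atoms only):
#' \itemize{
#'   \item donor: N or O bearing at least one (implicit) hydrogen;
#'   \item acceptor: O with non-positive charge, or N with non-positive
#'     charge that is not a pyrrole-type aromatic NH;
#'   \item positive ionizable: formal charge > 0, or an aliphatic amine N
#'     (all bonds single, no aromatic neighbour, no neighbouring carbon
#'     double-bonded to O/N/S);
#'   \item negative ionizable: formal charge < 0, or a carboxylic acid
#'     hydroxyl oxygen;
#'   \item hydrophobe: carbon with no N/O neighbour, or Cl/Br/I;
#'   \item aromatic: the aromatic flag.
#' }
#'
#' @param mol a [MolecularGraph-class].
#' @return Logical matrix, atoms x 6 classes.
#' @examples
#' assignPharmacophoreClasses(parseSmiles("CCO"))  # O row: donor + acceptor
#' @export
assignPharmacophoreClasses <- function(mol) {
  a <- mol@atoms
  n <- nrow(a)
  h <- implicitHydrogens(mol)
  b <- mol@bonds
  nbrs <- vector("list", n)
  nbro <- vector("list", n)  # bond orders parallel to nbrs
  for (k in seq_len(nrow(b))) {
    nbrs[[b$i[k]]] <- c(nbrs[[b$i[k]]], b$j[k]); nbro[[b$i[k]]] <- c(nbro[[b$i[k]]], b$order[k])
    nbrs[[b$j[k]]] <- c(nbrs[[b$j[k]]], b$i[k]); nbro[[b$j[k]]] <- c(nbro[[b$j[k]]], b$order[k])
  }
  el <- a$element
  out <- matrix(FALSE, n, length(.PHARM_CLASSES),
                dimnames = list(NULL, .PHARM_CLASSES))
  hasDoubleToHet <- vapply(seq_len(n), function(i) {
    # is atom i a carbon double-bonded to O/N/S? (carbonyl-like)
    el[i] == "C" && any(nbro[[i]] == 2L & el[nbrs[[i]]] %in% c("O", "N", "S"))
  }, logical(1))
  for (i in seq_len(n)) {
    e <- el[i]; chg <- a$charge[i]; ar <- a$aromatic[i]
    nb <- nbrs[[i]]; no <- nbro[[i]]
    if (e %in% c("N", "O") && h[i] >= 1L) out[i, "donor"] <- TRUE
    if (e == "O" && chg <= 0L) out[i, "acceptor"] <- TRUE
    if (e == "N" && chg <= 0L && !(ar && h[i] >= 1L)) out[i, "acceptor"] <- TRUE
    if (chg > 0L) out[i, "posIonizable"] <- TRUE
    if (e == "N" && !ar && chg == 0L && all(no == 1L) &&
        !any(a$aromatic[nb]) && !any(hasDoubleToHet[nb]))
      out[i, "posIonizable"] <- TRUE
    if (chg < 0L) out[i, "negIonizable"] <- TRUE
    if (e == "O" && h[i] >= 1L && any(hasDoubleToHet[nb] & el[nb] == "C"))
      out[i, "negIonizable"] <- TRUE  # carboxylic acid OH
    if (e == "C" && !any(el[nb] %in% c("N", "O"))) out[i, "hydrophobe"] <- TRUE
    if (e %in% c("Cl", "Br", "I")) out[i, "hydrophobe"] <- TRUE
    if (ar) out[i, "aromatic"] <- TRUE
  }
  out
}

#' Fixed column names of the 147 pharmacophore-pair fingerprint bits
#'
#' @return Character vector of length 147, in canonical order: unordered
#'   class pairs (class order donor, acceptor, posIonizable, negIonizable,
#'   hydrophobe, aromatic), each with bins d1..d6 and d7plus.
#' @export
fingerprintColumnNames <- function() {
  cols <- character()
  for (p in seq_along(.PHARM_CLASSES))
    for (q in p:length(.PHARM_CLASSES))
      cols <- c(cols, paste0("PP_", .PHARM_CLASSES[p], "_", .PHARM_CLASSES[q],
                             "_d", c(1:6, "7plus")))
  cols
}

#' Pharmacophore-pair fingerprint (147 bits)
#'
#' Bit for (unordered class pair, distance bin) is 1 iff some pair of
#' *distinct* atoms carrying those classes lies at that binned shortest-path
#' (bond count) distance. An atom carrying both classes of a pair does not by
#' itself set a bit; atom pairs in different fragments are ignored.
#'
#' @param mol a [MolecularGraph-class].
#' @param classes optionally, a precomputed class matrix from
#'   [assignPharmacophoreClasses()].
#' @return Named integer vector of 147 bits.
#' @examples
#' sum(pharmacophoreFingerprint(parseSmiles("C")))  # methane: all bits 0
#' @export
pharmacophoreFingerprint <- function(mol, classes = assignPharmacophoreClasses(mol)) {
  bits <- setNames(integer(147L), fingerprintColumnNames())
  n <- nrow(mol@atoms)
  featAtoms <- which(rowSums(classes) > 0L)
  if (length(featAtoms) >= 2L) {
    d <- .cpp_dist_matrix(n, mol@bonds$i - 1L, mol@bonds$j - 1L)
    nc <- length(.PHARM_CLASSES)
    pairIndex <- matrix(0L, nc, nc)
    idx <- 0L
    for (p in seq_len(nc)) for (q in p:nc) {
      idx <- idx + 1L
      pairIndex[p, q] <- idx; pairIndex[q, p] <- idx
    }
    for (ii in seq_along(featAtoms)) {
      for (jj in seq_len(ii - 1L)) {
        i <- featAtoms[ii]; j <- featAtoms[jj]
        dij <- d[i, j]
        if (dij < 1L) next
        bin <- min(dij, 7L)
        ci <- which(classes[i, ]); cj <- which(classes[j, ])
        for (p in ci) for (q in cj)
          bits[(pairIndex[p, q] - 1L) * 7L + bin] <- 1L
      }
    }
  }
  bits
}
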