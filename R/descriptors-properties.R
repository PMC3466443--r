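# Whole-molecule property descriptors (the 8-column property block).
# Fixed order: molecular weight, calculated logP (coarse additive scheme),
# topological polar surface area (Ertl fragment contributions, N/O subset),
# H-bond donor count, H-bond acceptor count, rotatable bond count,
# ring count (cyclomatic number), heavy atom count.

.PROPERTY_NAMES <- c("MW", "logP", "TPSA", "HBD", "HBA", "RotB", "Rings", "HeavyAtoms")

.tpsaAtom <- function(mol, i, h, nbro_i, deg_i) {
  a <- mol@atoms
  e <- a$element[i]; chg <- a$charge[i]; ar <- a$aromatic[i]
  hs <- h[i]
  nd <- sum(nbro_i == 2L); nt <- sum(nbro_i == 3L)
  if (e == "N") {
    if (chg > 0L) {
      if (hs >= 3L) return(27.64)
      if (hs == 2L) return(16.61)
      if (hs == 1L) return(4.44)
      return(0.00)
    }
    if (ar) {
      if (hs >= 1L) return(15.79)
      if (deg_i >= 3L) return(4.93)
      return(12.89)
    }
    if (nt >= 1L) return(23.79)
    if (nd >= 1L) return(if (hs >= 1L) 23.85 else 12.36)
    if (hs >= 2L) return(26.02)
    if (hs == 1L) return(12.03)
    return(3.24)
  }
  if (e == "O") {
    if (chg < 0L) return(23.06)
    if (ar) return(13.14)
    if (nd >= 1L) return(17.07)
    if (hs >= 1L) return(20.23)
    return(9.23)
  }
  0
}

#' Whole-molecule property descriptors (8 values)
#'
#' @param mol a [MolecularGraph-class].
#' @return Named numeric vector: \code{MW}, \code{logP}, \code{TPSA},
#'   \code{HBD}, \code{HBA}, \code{RotB}, \code{Rings}, \code{HeavyAtoms}.
#'   Donor/acceptor counts are counts of donor/acceptor *atoms* under the
#'   pharmacophore rules; rotatable bonds are non-ring single bonds between
#'   two non-terminal heavy atoms; ring count is the cyclomatic number.
#' @examples
#' propertyDescriptors(parseSmiles("c1ccc(cc1)-c1ccccc1"))  # biphenyl
#' @export
propertyDescriptors <- function(mol) {
  a <- mol@atoms
  n <- nrow(a)
  h <- implicitHydrogens(mol)
  b <- mol@bonds
  deg <- if (nrow(b)) tabulate(c(b$i, b$j), n) else integer(n)
  nbro <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nbro[[b$i[k]]] <- c(nbro[[b$i[k]]], b$order[k])
    nbro[[b$j[k]]] <- c(nbro[[b$j[k]]], b$order[k])
  }
  mw <- sum(.ELEMENTS[a$element, "mass"]) + .H_MASS * sum(h)
  logp <- sum(.logpContrib(mol))
  tpsa <- sum(vapply(seq_len(n), function(i)
    .tpsaAtom(mol, i, h, nbro[[i]] %||% integer(), deg[i]), numeric(1)))
  cls <- assignPharmacophoreClasses(mol)
  hbd <- sum(cls[, "donor"])
  hba <- sum(cls[, "acceptor"])
  rot <- 0L
  nring <- 0L
  if (nrow(b)) {
    inRing <- .cpp_ring_bonds(n, b$i - 1L, b$j - 1L)
    rot <- sum(!inRing & b$order == 1L & deg[b$i] >= 2L & deg[b$j] >= 2L)
    nfrag <- length(unique(fragmentIds(mol)))
    nring <- nrow(b) - n + nfrag
  }
  setNames(c(mw, logp, tpsa, hbd, hba, rot, nring, n), .PROPERTY_NAMES)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
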