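# Graph-level utilities on MolecularGraph objects.

#' @rdname accessors
#' @export
setMethod("atoms", "MolecularGraph", function(x) x@atoms)

#' @rdname accessors
#' @export
setMethod("bonds", "MolecularGraph", function(x) x@bonds)

#' @rdname accessors
#' @export
setMethod("molName", "MolecularGraph", function(x) x@name)

#' @rdname accessors
#' @export
setMethod("heavyAtomCount", "MolecularGraph", function(x) nrow(x@atoms))

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf("MolecularGraph%s: %d heavy atoms, %d bonds\n",
              if (nzchar(object@name)) paste0(" '", object@name, "'") else "",
              nrow(object@atoms), nrow(object@bonds)))
  smi <- tryCatch(molToSmiles(object), error = function(e) NA_character_)
  if (!is.na(smi)) cat("  ", smi, "\n", sep = "")
})

# packed 0-based representation handed to the C++ kernels
.molPack <- function(mol) {
  a <- mol@atoms; b <- mol@bonds
  list(elem = .atomicNumber(a$element), chg = a$charge, arom = a$aromatic,
       bi = b$i - 1L, bj = b$j - 1L, bo = b$order)
}

.packLibrary <- function(mols) lapply(mols, .molPack)

#' Connected fragments of a molecule
#'
#' @param mol a [MolecularGraph-class].
#' @return Integer vector assigning each atom a fragment id (1-based).
#' @export
fragmentIds <- function(mol) {
  n <- nrow(mol@atoms)
  if (n == 0L) return(integer())
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol@bonds))) {
    i <- mol@bonds$i[k]; j <- mol@bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[u]]; nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Extract an induced subgraph on a set of atoms
#'
#' @param mol a [MolecularGraph-class].
#' @param keep integer atom indices to keep.
#' @param name name for the result.
#' @return A [MolecularGraph-class] on the kept atoms (bonds between them).
#' @export
inducedSubgraph <- function(mol, keep, name = mol@name) {
  keep <- sort(unique(as.integer(keep)))
  idx <- match(seq_len(nrow(mol@atoms)), keep)
  b <- mol@bonds
  sel <- b$i %in% keep & b$j %in% keep
  MolecularGraph(mol@atoms[keep, , drop = FALSE],
                 data.frame(i = idx[b$i[sel]], j = idx[b$j[sel]], order = b$order[sel]),
                 name = name)
}

#' Reduce a molecule to its largest connected fragment
#'
#' Salt/solvate records are reduced to the largest fragment (ties broken by
#' the earliest fragment) before descriptor or MCS work.
#'
#' @param mol a [MolecularGraph-class].
#' @return A connected [MolecularGraph-class].
#' @export
largestFragment <- function(mol) {
  comp <- fragmentIds(mol)
  if (length(unique(comp)) <= 1L) return(mol)
  sizes <- tabulate(comp)
  inducedSubgraph(mol, which(comp == which.max(sizes)))
}

#' Implicit hydrogen counts
#'
#' Hydrogens are implicit: for atoms without an explicit SMILES hydrogen
#' count, the count is the gap between the smallest standard valence
#' (adjusted by formal charge) and the bonded order sum (aromatic bonds count
#' 1.5, summed then floored).
#'
#' @param mol a [MolecularGraph-class].
#' @return Integer vector of hydrogen counts per heavy atom.
#' @export
implicitHydrogens <- function(mol) {
  a <- mol@atoms
  n <- nrow(a)
  bosum <- numeric(n)
  b <- mol@bonds
  if (nrow(b)) {
    ov <- ifelse(b$order == 4L, 1.5, b$order)
    for (k in seq_len(nrow(b))) {
      bosum[b$i[k]] <- bosum[b$i[k]] + ov[k]
      bosum[b$j[k]] <- bosum[b$j[k]] + ov[k]
    }
  }
  bosum <- floor(bosum)
  h <- integer(n)
  for (i in seq_len(n)) {
    if (!is.na(a$hcount[i])) { h[i] <- a$hcount[i]; next }
    vals <- .VALENCES[[a$element[i]]]
    # charge extends/contracts the valence: N+ 4, O- 1, O+ 3, C+/C- 3, ...
    adj <- if (a$element[i] %in% c("N", "O", "P", "S")) a$charge[i] else -abs(a$charge[i])
    vals <- vals + adj
    v <- vals[vals >= bosum[i]][1]
    h[i] <- if (is.na(v)) 0L else as.integer(v - bosum[i])
  }
  h
}

#' Canonical string code of a molecular graph
#'
#' Two molecules have equal codes iff they are isomorphic under the
#' (element, charge, aromatic, bond order) labelling. Used for deduplication,
#' deterministic tie-breaking and isomorphism checks.
#'
#' @param mol a [MolecularGraph-class].
#' @return A single character string.
#' @export
canonicalCode <- function(mol) .cpp_canonical_code(.molPack(mol))

#' Test two molecules for graph isomorphism
#'
#' @param a,b [MolecularGraph-class] objects.
#' @return Logical.
#' @export
molsIsomorphic <- function(a, b) {
  nrow(a@atoms) == nrow(b@atoms) && nrow(a@bonds) == nrow(b@bonds) &&
    canonicalCode(a) == canonicalCode(b)
}

#' Subgraph (substructure) matching
#'
#' Tests whether \code{query} embeds in \code{target} as a subgraph
#' monomorphism. Atoms match on (element, aromatic flag); bonds match on
#' order with aromatic treated as its own order; formal charge is ignored.
#'
#' @param query,target [MolecularGraph-class] objects.
#' @return Logical.
#' @examples
#' isSubstructure(parseSmiles("c1ccccc1"), parseSmiles("Cc1ccccc1"))  # TRUE
#' isSubstructure(parseSmiles("Cc1ccccc1"), parseSmiles("c1ccccc1"))  # FALSE
#' @export
isSubstructure <- function(query, target) {
  stopifnot(is(query, "MolecularGraph"), is(target, "MolecularGraph"))
  if (nrow(query@atoms) == 0L || nrow(target@atoms) == 0L)
    stop("both graphs must be non-empty")
  .cpp_is_substructure(.molPack(query), .molPack(target))
}

# CompoundLibrary methods ----------------------------------------------------

#' @rdname accessors
#' @export
setMethod("compoundIds", "CompoundLibrary", function(x) x@ids)

#' @rdname accessors
#' @export
setMethod("molecules", "CompoundLibrary", function(x) setNames(x@mols, x@ids))

#' @rdname accessors
#' @export
setMethod("compoundProperties", "CompoundLibrary", function(x) {
  p <- x@properties
  rownames(p) <- x@ids
  p
})

#' @rdname accessors
#' @export
setMethod("length", "CompoundLibrary", function(x) length(x@ids))

#' @export
#' @rdname accessors
#' @param i index vector (integer, logical or compound ids).
setMethod("[", "CompoundLibrary", function(x, i, ...) {
  if (is.character(i)) i <- match(i, x@ids)
  new("CompoundLibrary", ids = x@ids[i], mols = x@mols[i],
      properties = x@properties[i, , drop = FALSE])
})

#' @export
#' @rdname accessors
setMethod("[[", "CompoundLibrary", function(x, i, ...) {
  if (is.character(i)) i <- match(i, x@ids)
  x@mols[[i]]
})

setMethod("show", "CompoundLibrary", function(object) {
  cat(sprintf("CompoundLibrary: %d compounds, %d property column(s)\n",
              length(object@ids), ncol(object@properties)))
  if (length(object@ids))
    cat("  ids: ", paste(head(object@ids, 5), collapse = ", "),
        if (length(object@ids) > 5) ", ..." else "", "\n", sep = "")
})

#' Standardize a library for descriptor / MCS work
#'
#' Reduces multi-fragment molecules (salts) to their largest connected
#' fragment, with a message reporting how many records were desalted.
#'
#' @param library a [CompoundLibrary-class].
#' @return A [CompoundLibrary-class] of connected molecules.
#' @export
standardizeLibrary <- function(library) {
  multi <- vapply(library@mols, function(m) max(c(fragmentIds(m), 1L)) > 1L, logical(1))
  if (any(multi)) {
    message(sum(multi), " multi-fragment molecule(s) reduced to largest fragment")
    library@mols[multi] <- lapply(library@mols[multi], largestFragment)
  }
  library
}
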