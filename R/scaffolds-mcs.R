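# Maximum common connected substructure between two molecules.
#
# Exact search: maximum c-connected clique on the modular product graph
# (element + aromatic flag on atoms, bond order with aromatic distinct on
# edges), with a distinct-atom upper bound. Molecules beyond `exact_atoms`
# heavy atoms, or searches exceeding the node budget, fall back to the best
# clique found so far and are flagged approximate.

#' Maximum common substructure of two molecules
#'
#' Returns a largest (by heavy-atom count) connected subgraph embeddable in
#' both molecules under the matching policy of [isSubstructure()]. The
#' reported size is symmetric in the arguments; the returned graph is the
#' mapped subgraph of \code{a} (its bonds are those common to both sides).
#'
#' @param a,b non-empty [MolecularGraph-class] objects.
#' @param min_atoms report the MCS only if it has at least this many atoms;
#'   below that the call returns \code{NULL} cheaply. Default 1 (always
#'   report; an empty graph results only when no atom is shared).
#' @param exact_atoms molecules up to this size are searched exactly
#'   (default 40); larger inputs use the truncated search.
#' @param node_budget search-node cap (default 2e6).
#' @return A [MolecularGraph-class] (possibly with 0 atoms), or \code{NULL}
#'   when the MCS is provably smaller than \code{min_atoms}. Attributes:
#'   \code{size}, \code{exact}.
#' @examples
#' mcs(parseSmiles("CCO"), parseSmiles("CCCO"))   # 3 atoms: C-C-O
#' @export
mcs <- function(a, b, min_atoms = 1L, exact_atoms = 40L, node_budget = 2e6) {
  stopifnot(is(a, "MolecularGraph"), is(b, "MolecularGraph"))
  if (nrow(a@atoms) == 0L || nrow(b@atoms) == 0L)
    stop("both molecules must be non-empty")
  budget <- if (max(nrow(a@atoms), nrow(b@atoms)) > exact_atoms)
    min(node_budget, 2e5) else node_budget
  res <- .cpp_mcs(.molPack(a), .molPack(b), as.integer(min_atoms), budget)
  if (!res$found) {
    if (min_atoms > 1L) return(NULL)
    res <- list(size = 0L, exact = res$exact)   # no shared atom: empty graph
  }
  if (res$size == 0L) {
    out <- MolecularGraph(data.frame(element = character(), charge = integer(),
                                     aromatic = logical(), hcount = integer()))
    attr(out, "size") <- 0L; attr(out, "exact") <- res$exact
    return(out)
  }
  amap <- res$amap + 1L
  bmap <- res$bmap + 1L
  # keep only the bonds realised on both sides (the clique's c-edges)
  ab <- a@bonds
  keyA <- paste(pmin(ab$i, ab$j), pmax(ab$i, ab$j))
  bb <- b@bonds
  keyB <- paste(pmin(bb$i, bb$j), pmax(bb$i, bb$j))
  ordB <- setNames(bb$order, keyB)
  sel <- integer(0)
  posA <- match(seq_len(nrow(a@atoms)), amap)  # atom in a -> clique position
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  for (k in seq_len(nrow(ab))) {
    pi <- posA[ab$i[k]]; pj <- posA[ab$j[k]]
    if (is.na(pi) || is.na(pj)) next
    kb <- paste(min(bmap[pi], bmap[pj]), max(bmap[pi], bmap[pj]))
    ob <- ordB[kb]
    if (!is.na(ob) && ob == ab$order[k]) {
      bi <- c(bi, pi); bj <- c(bj, pj); bo <- c(bo, ab$order[k])
    }
  }
  atomsA <- a@atoms[amap, , drop = FALSE]
  atomsA$hcount <- NA_integer_  # substructure: hydrogen counts unconstrained
  out <- MolecularGraph(atomsA, data.frame(i = bi, j = bj, order = bo))
  attr(out, "size") <- res$size
  attr(out, "exact") <- res$exact
  out
}
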