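# Independent brute-force oracles and small-graph utilities used across the
# suite. Everything here is deliberately naive: exhaustive enumeration, no
# clever pruning, so the fast implementations can be checked against it.

# random labelled graph with valid MolecularGraph structure (valence not
# enforced; matching and MCS do not require it)
randomMolGraph <- function(n, elements = c("C", "C", "C", "N", "O", "S"),
                           extra_edges = 2L) {
  stopifnot(n >= 1L)
  atoms <- data.frame(element = sample(elements, n, replace = TRUE),
                      charge = 0L, aromatic = FALSE, hcount = NA_integer_)
  bonds <- NULL
  if (n > 1L) {
    # random spanning tree
    bi <- integer(); bj <- integer()
    for (v in 2:n) {
      u <- sample(v - 1L, 1L)
      bi <- c(bi, u); bj <- c(bj, v)
    }
    # a few extra edges, avoiding duplicates
    for (t in seq_len(sample(0:extra_edges, 1L))) {
      u <- sample(n, 2L)
      key <- paste(min(u), max(u))
      if (!key %in% paste(pmin(bi, bj), pmax(bi, bj))) {
        bi <- c(bi, u[1]); bj <- c(bj, u[2])
      }
    }
    bonds <- data.frame(i = bi, j = bj,
                        order = sample(c(1L, 1L, 1L, 2L), length(bi), replace = TRUE))
  }
  MolecularGraph(atoms, bonds)
}

# exhaustive subgraph-monomorphism oracle: enumerate injective mappings of
# query atoms into target atoms (element + aromatic compatible), then check
# every query bond maps onto a target bond of equal order
oracleIsSubstructure <- function(query, target) {
  qa <- atoms(query); ta <- atoms(target)
  qb <- bonds(query)
  nq <- nrow(qa); nt <- nrow(ta)
  if (nq > nt) return(FALSE)
  tOrder <- matrix(0L, nt, nt)
  tb <- bonds(target)
  for (k in seq_len(nrow(tb))) {
    tOrder[tb$i[k], tb$j[k]] <- tb$order[k]
    tOrder[tb$j[k], tb$i[k]] <- tb$order[k]
  }
  checkBonds <- function(map) {
    for (k in seq_len(nrow(qb)))
      if (tOrder[map[qb$i[k]], map[qb$j[k]]] != qb$order[k]) return(FALSE)
    TRUE
  }
  found <- FALSE
  recurse <- function(pos, map, used) {
    if (found) return()
    if (pos > nq) {
      if (checkBonds(map)) found <<- TRUE
      return()
    }
    for (v in seq_len(nt)) {
      if (used[v]) next
      if (ta$element[v] != qa$element[pos] || ta$aromatic[v] != qa$aromatic[pos]) next
      map[pos] <- v; used[v] <- TRUE
      recurse(pos + 1L, map, used)
      used[v] <- FALSE
      if (found) return()
    }
  }
  recurse(1L, integer(nq), logical(nt))
  found
}

# exhaustive maximum-common-connected-subgraph size oracle: enumerate every
# connected subgraph of `a` (atom set + bond subset, grown bond by bond,
# deduplicated), keep those embeddable in `b` by the mapping oracle, and
# return the maximum atom count
oracleMcsSize <- function(a, b) {
  ab <- bonds(a)
  na <- nrow(atoms(a))
  best <- 0L
  # single shared atoms
  for (i in seq_len(na)) {
    sub <- inducedSubgraph(a, i)
    sub@bonds <- sub@bonds[0, ]
    if (oracleIsSubstructure(sub, b)) { best <- 1L; break }
  }
  if (nrow(ab) == 0L || best == 0L) return(best)
  seen <- new.env(parent = emptyenv())
  asGraph <- function(bondIdx) {
    atomsIdx <- sort(unique(c(ab$i[bondIdx], ab$j[bondIdx])))
    remap <- match(seq_len(na), atomsIdx)
    MolecularGraph(atoms(a)[atomsIdx, , drop = FALSE],
                   data.frame(i = remap[ab$i[bondIdx]], j = remap[ab$j[bondIdx]],
                              order = ab$order[bondIdx]))
  }
  grow <- function(bondIdx, atomSet) {
    key <- paste(sort(bondIdx), collapse = ",")
    if (!is.null(seen[[key]])) return()
    seen[[key]] <- TRUE
    g <- asGraph(bondIdx)
    if (oracleIsSubstructure(g, b)) best <<- max(best, length(atomSet))
    # extend by any bond touching the current atom set
    for (k in seq_len(nrow(ab))) {
      if (k %in% bondIdx) next
      if (ab$i[k] %in% atomSet || ab$j[k] %in% atomSet)
        grow(c(bondIdx, k), union(atomSet, c(ab$i[k], ab$j[k])))
    }
  }
  for (k in seq_len(nrow(ab))) grow(k, c(ab$i[k], ab$j[k]))
  best
}

# all-pairs Mann-Whitney AUC oracle (ties count 1/2)
oracleAuc <- function(labels, scores) {
  pos <- scores[labels == "active"]
  neg <- scores[labels == "inactive"]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# atom-order permutation preserving the molecule
permuteAtoms <- function(mol, perm) {
  a <- atoms(mol)[perm, , drop = FALSE]
  inv <- match(seq_len(nrow(a)), perm)
  b <- bonds(mol)
  MolecularGraph(a, data.frame(i = inv[b$i], j = inv[b$j], order = b$order),
                 name = molName(mol))
}

# small SDF fixture written to a temp file
writeToySDF <- function(path, corrupt_record = FALSE) {
  rec <- function(title, natoms, elements, bonds, props = NULL) {
    lines <- c(title, "  toy", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", natoms, nrow(bonds)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, elements))
    lines <- c(lines, sprintf("%3d%3d%3d  0", bonds$i, bonds$j, bonds$order))
    lines <- c(lines, "M  END")
    for (nm in names(props)) lines <- c(lines, paste0("> <", nm, ">"), props[[nm]], "")
    c(lines, "$$$$")
  }
  out <- c(
    rec("ethanol", 3, c("C", "C", "O"), data.frame(i = 1:2, j = 2:3, order = 1),
        list(PUBCHEM_ACTIVITY_SCORE = "87")),
    if (corrupt_record)
      c("broken", "  toy", "", "  5  1  0  0  0  0  0  0  0  0999 V2000",
        "garbage atom line", "M  END", "$$$$"),
    rec("propane", 3, c("C", "C", "C"), data.frame(i = 1:2, j = 2:3, order = 1)))
  writeLines(out, path)
  path
}
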