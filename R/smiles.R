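# SMILES input / output.
#
# The parser covers the organic subset (B C N O P S F Cl Br I), aromatic
# lowercase atoms, bracket atoms with isotope / chirality (both accepted and
# ignored: the pipeline is purely 2D), explicit hydrogen counts and formal
# charges, branches, ring closures (including %nn) and dot-separated
# fragments. Aromaticity written as lowercase is taken as-is; kekulized
# 5/6-membered rings are additionally perceived aromatic by an alternation
# rule so that e.g. "C1=CC=CC=C1" and "c1ccccc1" parse to the same graph.

.smilesError <- function(smiles, pos, what) {
  stop(sprintf("SMILES parse error at position %d ('%s') in \"%s\": %s",
               pos, substr(smiles, pos, pos), smiles, what), call. = FALSE)
}

#' Parse a SMILES string
#'
#' @param smiles single non-empty SMILES string.
#' @param name optional compound id stored on the molecule.
#' @param perceiveAromaticity also mark kekulized aromatic rings (alternating
#'   6-rings of C/N; 5-rings with two double bonds and one lone-pair
#'   heteroatom) as aromatic. Default TRUE.
#' @return A sanitized [MolecularGraph-class]; hydrogens implicit.
#' @examples
#' parseSmiles("CCO")        # ethanol: 3 atoms, 2 single bonds
#' parseSmiles("c1ccccc1")   # benzene: 6 aromatic atoms and bonds
#' @export
parseSmiles <- function(smiles, name = "", perceiveAromaticity = TRUE) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("empty SMILES string")
  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)

  elem <- character(); charge <- integer(); arom <- logical(); hcount <- integer()
  bi <- integer(); bj <- integer(); bo <- integer()
  prev <- NA_integer_
  pending <- NA_integer_          # explicit bond symbol awaiting the next atom
  stack <- integer()
  rings <- list()                 # closure digit -> list(atom, bond, pos)

  addBond <- function(i, j, order, pos) {
    if (i == j) .smilesError(smiles, pos, "ring bond forms a self-loop")
    bi <<- c(bi, i); bj <<- c(bj, j); bo <<- c(bo, order)
  }
  addAtom <- function(el, aromatic, chg, hc, pos) {
    elem <<- c(elem, el); charge <<- c(charge, chg)
    arom <<- c(arom, aromatic); hcount <<- c(hcount, hc)
    id <- length(elem)
    if (!is.na(prev)) {
      order <- pending
      if (is.na(order)) order <- if (arom[prev] && aromatic) 4L else 1L
      addBond(prev, id, order, pos)
    }
    pending <<- NA_integer_
    prev <<- id
  }
  closeRing <- function(num, pos) {
    key <- as.character(num)
    if (is.na(prev)) .smilesError(smiles, pos, "ring closure before any atom")
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending, pos = pos)
    } else {
      open <- rings[[key]]
      order <- pending
      if (is.na(order)) order <- open$bond
      else if (!is.na(open$bond) && open$bond != order)
        .smilesError(smiles, pos, "conflicting ring-closure bond orders")
      if (is.na(order)) order <- if (arom[open$atom] && arom[prev]) 4L else 1L
      addBond(open$atom, prev, order, pos)
      rings[[key]] <<- NULL
    }
    pending <<- NA_integer_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      if (is.na(prev)) .smilesError(smiles, i, "branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) .smilesError(smiles, i, "unmatched ')'")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending <- 1L; i <- i + 1L
    } else if (ch == "=") {
      pending <- 2L; i <- i + 1L
    } else if (ch == "#") {
      pending <- 3L; i <- i + 1L
    } else if (ch == ":") {
      pending <- 4L; i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending <- NA_integer_; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      closeRing(as.integer(ch), i); i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n || !grepl("^[0-9]{2}$", substr(smiles, i + 1L, i + 2L)))
        .smilesError(smiles, i, "'%' must be followed by two digits")
      closeRing(as.integer(substr(smiles, i + 1L, i + 2L)), i)
      i <- i + 3L
    } else if (ch == "[") {
      close <- regexpr("]", substr(smiles, i, n), fixed = TRUE)
      if (close < 0) .smilesError(smiles, i, "unclosed bracket atom")
      body <- substr(smiles, i + 1L, i + close - 2L)
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?([+-][0-9]*|\\++|-+)?(:[0-9]+)?$", body))[[1]]
      if (!length(m)) .smilesError(smiles, i, paste0("malformed bracket atom [", body, "]"))
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      el <- if (aromatic) toupper(sym) else sym
      if (!el %in% .ELEMENTS$symbol) .smilesError(smiles, i, paste("unsupported element", sym))
      hc <- if (m[5] == "") 0L
            else if (m[5] == "H") 1L
            else as.integer(substr(m[5], 2L, nchar(m[5])))
      chg <- 0L
      if (m[6] != "") {
        sgn <- if (substr(m[6], 1L, 1L) == "+") 1L else -1L
        mag <- gsub("[+-]", "", m[6])
        chg <- sgn * (if (nzchar(mag)) as.integer(mag) else nchar(m[6]))
      }
      addAtom(el, aromatic, chg, hc, i)
      i <- i + close
    } else if (grepl("[A-Za-z]", ch)) {
      two <- substr(smiles, i, i + 1L)
      if (two %in% c("Cl", "Br")) {
        addAtom(two, FALSE, 0L, NA_integer_, i); i <- i + 2L
      } else if (ch %in% .ORGANIC_SUBSET) {
        addAtom(ch, FALSE, 0L, NA_integer_, i); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        addAtom(toupper(ch), TRUE, 0L, NA_integer_, i); i <- i + 1L
      } else .smilesError(smiles, i, "unexpected atom symbol")
    } else .smilesError(smiles, i, "unexpected character")
  }
  if (length(stack)) .smilesError(smiles, n, "unclosed branch '('")
  if (length(rings)) .smilesError(smiles, n, paste("unclosed ring closure(s):",
                                                   paste(names(rings), collapse = ", ")))
  if (!length(elem)) stop("SMILES contains no atoms: ", smiles)

  mol <- MolecularGraph(
    data.frame(element = elem, charge = charge, aromatic = arom, hcount = hcount,
               stringsAsFactors = FALSE),
    if (length(bi)) data.frame(i = bi, j = bj, order = bo) else NULL,
    name = name)
  if (perceiveAromaticity) mol <- .perceiveAromaticity(mol)
  mol
}

# Mark kekulized aromatic rings: 6-rings of neutral C/N where every ring atom
# has exactly one in-ring double bond; 5-rings with two alternating double
# bonds whose remaining atom is a lone-pair N/O/S. Runs ring by ring so fused
# kekulized systems (naphthalene, quinoline) are covered.
.perceiveAromaticity <- function(mol) {
  b <- mol@bonds
  if (!nrow(b)) return(mol)
  ring <- .cpp_ring_bonds(nrow(mol@atoms), b$i - 1L, b$j - 1L)
  if (!any(ring)) return(mol)
  rb <- b[ring, , drop = FALSE]
  adj <- vector("list", nrow(mol@atoms))
  for (k in seq_len(nrow(rb))) {
    adj[[rb$i[k]]] <- rbind(adj[[rb$i[k]]], c(rb$j[k], rb$order[k]))
    adj[[rb$j[k]]] <- rbind(adj[[rb$j[k]]], c(rb$i[k], rb$order[k]))
  }
  cycles <- list()
  # enumerate simple cycles of length 5-6 whose smallest atom is the start
  dfs <- function(start, path) {
    u <- path[length(path)]
    for (r in seq_len(NROW(adj[[u]]))) {
      v <- adj[[u]][r, 1]
      if (v == start && length(path) >= 5L) {
        cycles[[length(cycles) + 1L]] <<- path
      } else if (length(path) < 6L && v > start && !v %in% path) {
        dfs(start, c(path, v))
      }
    }
  }
  starts <- sort(unique(c(rb$i, rb$j)))
  for (s in starts) if (NROW(adj[[s]]) >= 2L) dfs(s, s)
  if (!length(cycles)) return(mol)

  a <- mol@atoms
  bondKey <- paste(pmin(b$i, b$j), pmax(b$i, b$j))
  orderOf <- function(i, j) b$order[match(paste(min(i, j), max(i, j)), bondKey)]
  aromAtoms <- logical(nrow(a)); aromBonds <- logical(nrow(b))
  for (cyc in unique(cycles)) {
    m <- length(cyc)
    nxt <- c(cyc[-1], cyc[1])
    orders <- mapply(orderOf, cyc, nxt)
    if (any(is.na(orders)) || !all(orders %in% c(1L, 2L, 4L))) next
    # in-ring double-bond count per cycle atom
    dbl <- integer(m)
    for (k in seq_len(m)) {
      dbl[k] <- dbl[k] + (orders[k] == 2L)
      kp <- if (k == 1L) m else k - 1L
      dbl[k] <- dbl[k] + (orders[kp] == 2L)
    }
    ok <- if (m == 6L) {
      all(dbl == 1L) && all(a$element[cyc] %in% c("C", "N")) && all(a$charge[cyc] == 0L)
    } else if (m == 5L) {
      sum(orders == 2L) == 2L && sum(dbl == 0L) == 1L &&
        a$element[cyc[dbl == 0L]] %in% c("N", "O", "S") &&
        all(a$element[cyc] %in% c("C", "N", "O", "S"))
    } else FALSE
    if (!ok) next
    aromAtoms[cyc] <- TRUE
    for (k in seq_len(m))
      aromBonds[match(paste(min(cyc[k], nxt[k]), max(cyc[k], nxt[k])), bondKey)] <- TRUE
  }
  if (!any(aromAtoms)) return(mol)
  # pin hydrogen counts before bond orders change (pyrrole N keeps its H)
  h <- implicitHydrogens(mol)
  a$hcount[aromAtoms & is.na(a$hcount)] <- h[aromAtoms & is.na(a$hcount)]
  a$aromatic <- a$aromatic | aromAtoms
  b$order[aromBonds] <- 4L
  MolecularGraph(a, b, name = mol@name)
}

#' Write a molecule as SMILES
#'
#' Not canonical across isomorphic graphs in general (use [canonicalCode()]
#' for identity), but deterministic for a given atom order, and guaranteed to
#' re-parse to an isomorphic graph.
#'
#' @param mol a [MolecularGraph-class].
#' @param canonical order atoms by canonical rank first, so isomorphic graphs
#'   with permuted atoms yield identical strings in almost all cases.
#' @return A SMILES string.
#' @export
molToSmiles <- function(mol, canonical = TRUE) {
  n <- nrow(mol@atoms)
  if (n == 0L) stop("cannot write an empty molecule")
  a <- mol@atoms
  b <- mol@bonds
  h <- implicitHydrogens(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    adj[[b$i[k]]] <- rbind(adj[[b$i[k]]], c(b$j[k], b$order[k]))
    adj[[b$j[k]]] <- rbind(adj[[b$j[k]]], c(b$i[k], b$order[k]))
  }
  rank <- seq_len(n)
  if (canonical && n > 1L) {
    # stable deterministic ordering: element, aromatic, charge, degree
    deg <- vapply(adj, NROW, integer(1))
    rank <- order(a$element, !a$aromatic, a$charge, -deg)
    rank <- match(seq_len(n), rank)  # atom -> priority (lower = earlier root)
  }

  defaultH <- function(i) {
    vals <- .VALENCES[[a$element[i]]]
    adjv <- if (a$element[i] %in% c("N", "O", "P", "S")) a$charge[i] else -abs(a$charge[i])
    vals <- vals + adjv
    bosum <- if (NROW(adj[[i]])) floor(sum(ifelse(adj[[i]][, 2] == 4L, 1.5, adj[[i]][, 2]))) else 0
    v <- vals[vals >= bosum][1]
    if (is.na(v)) 0L else as.integer(v - bosum)
  }
  atomToken <- function(i) {
    sym <- a$element[i]
    lower <- a$aromatic[i]
    shown <- if (lower) tolower(sym) else sym
    bare <- sym %in% .ORGANIC_SUBSET && a$charge[i] == 0L && h[i] == defaultH(i) &&
      !(lower && !sym %in% .AROMATIC_ELEMS)
    if (bare) return(shown)
    chg <- a$charge[i]
    paste0("[", shown,
           if (h[i] == 1L) "H" else if (h[i] > 1L) paste0("H", h[i]) else "",
           if (chg > 0L) paste0("+", if (chg > 1L) chg else "") else "",
           if (chg < 0L) paste0("-", if (chg < -1L) -chg else "") else "", "]")
  }
  bondToken <- function(i, j, order) {
    if (order == 2L) "=" else if (order == 3L) "#"
    else if (order == 4L) { if (a$aromatic[i] && a$aromatic[j]) "" else ":" }
    else { if (a$aromatic[i] && a$aromatic[j]) "-" else "" }
  }

  visited <- logical(n)
  ringNum <- 0L
  ringLabels <- vector("list", n)   # atom -> ring closure tokens to emit
  treeChild <- vector("list", n)
  parentOf <- rep(NA_integer_, n)
  emit <- character()

  nextDigit <- function() {
    ringNum <<- ringNum + 1L
    if (ringNum <= 9L) as.character(ringNum) else paste0("%", ringNum)
  }

  writeFrom <- function(root) {
    # iterative DFS building the spanning tree + ring closures
    orderNb <- function(u) {
      nb <- adj[[u]]
      if (!NROW(nb)) return(nb)
      nb[order(rank[nb[, 1]]), , drop = FALSE]
    }
    # first pass: depth-first spanning tree & ring-closure bonds
    edgesSeen <- new.env(parent = emptyenv())
    visited[root] <<- TRUE
    dfsBuild <- function(u) {
      nb <- orderNb(u)
      for (r in seq_len(NROW(nb))) {
        v <- nb[r, 1]; o <- nb[r, 2]
        ek <- paste(min(u, v), max(u, v))
        if (!is.null(edgesSeen[[ek]])) next
        edgesSeen[[ek]] <- TRUE
        if (!visited[v]) {
          visited[v] <<- TRUE
          parentOf[v] <<- u
          treeChild[[u]] <<- c(treeChild[[u]], v)
          dfsBuild(v)
        } else {
          d <- nextDigit()
          tok <- paste0(bondToken(u, v, o), d)
          ringLabels[[u]] <<- c(ringLabels[[u]], tok)
          ringLabels[[v]] <<- c(ringLabels[[v]], tok)
        }
      }
    }
    dfsBuild(root)
    # second pass: emit string recursively over the spanning tree
    emitAtom <- function(u) {
      s <- paste0(atomToken(u), paste(ringLabels[[u]], collapse = ""))
      kids <- treeChild[[u]]
      if (length(kids)) {
        parts <- vapply(kids, function(v) {
          o <- adj[[u]][match(v, adj[[u]][, 1]), 2]
          paste0(bondToken(u, v, o), emitAtom(v))
        }, character(1))
        if (length(parts) > 1L)
          s <- paste0(s, paste0("(", parts[-length(parts)], ")", collapse = ""), parts[length(parts)])
        else s <- paste0(s, parts)
      }
      s
    }
    emitAtom(root)
  }

  frags <- character()
  repeat {
    todo <- which(!visited)
    if (!length(todo)) break
    root <- todo[order(rank[todo])][1]
    frags <- c(frags, writeFrom(root))
  }
  paste(frags, collapse = ".")
}

#' Read a SMILES file
#'
#' One molecule per line: a SMILES string optionally followed by whitespace
#' and an id. Blank lines and lines starting with '#' are skipped. Lines that
#' fail to parse are skipped with a message reporting the count.
#'
#' @param path file path.
#' @param perceiveAromaticity passed to [parseSmiles()].
#' @return A [CompoundLibrary-class].
#' @export
readSmilesFile <- function(path, perceiveAromaticity = TRUE) {
  if (!file.exists(path)) stop("cannot read SMILES file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  mols <- list(); ids <- character(); skipped <- 0L
  for (k in seq_along(lines)) {
    parts <- strsplit(lines[k], "[[:space:]]+")[[1]]
    id <- if (length(parts) > 1L) parts[2] else as.character(length(mols) + 1L)
    m <- tryCatch(parseSmiles(parts[1], name = id,
                              perceiveAromaticity = perceiveAromaticity),
                  error = function(e) NULL)
    if (is.null(m)) { skipped <- skipped + 1L; next }
    mols[[length(mols) + 1L]] <- m
    ids <- c(ids, id)
  }
  if (skipped) message(skipped, " line(s) skipped (unparsable SMILES)")
  if (!length(mols)) stop("no parsable molecules in ", path)
  CompoundLibrary(mols, ids = ids)
}

#' Write a library as a SMILES file
#'
#' @param library a [CompoundLibrary-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeSmilesFile <- function(library, path) {
  lines <- vapply(seq_along(library@ids), function(k)
    paste(molToSmiles(library@mols[[k]]), library@ids[k]), character(1))
  writeLines(lines, path)
  invisible(path)
}
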