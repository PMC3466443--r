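# Weighted Burden-number descriptors: extreme eigenvalues of the Burden
# connectivity matrix under three atomic weighting schemes (Pauling
# electronegativity, Gasteiger-style partial charge, additive logP atom
# contribution). Classical Burden construction: diagonal = atomic weight;
# bonded off-diagonal = 0.1 x bond order (aromatic = 1.5), +0.01 when either
# end is terminal; non-bonded pairs = 0.001.

# Gasteiger-Marsili PEOE coefficients (a, b, c) by element/hybridisation.
.PEOE <- list(
  H      = c(7.17, 6.24, -0.56),
  C.sp3  = c(7.98, 9.18, 1.88),
  C.sp2  = c(8.79, 9.32, 1.51),
  C.sp   = c(10.39, 9.45, 0.73),
  N.sp3  = c(11.54, 10.82, 1.36),
  N.sp2  = c(12.87, 11.15, 0.85),
  N.sp   = c(15.68, 11.70, -0.27),
  O.sp3  = c(14.18, 12.92, 1.39),
  O.sp2  = c(17.07, 13.79, 0.47),
  F      = c(14.66, 13.85, 2.31),
  Cl     = c(11.00, 9.69, 1.35),
  Br     = c(10.08, 8.47, 1.16),
  I      = c(9.90, 7.96, 0.96),
  S      = c(10.14, 9.13, 1.38),
  P      = c(8.90, 8.24, 0.96),
  B      = c(7.98, 9.18, 1.88),   # treated like sp3 carbon (rare)
  Si     = c(7.30, 6.57, 0.66)
)

.peoeKey <- function(element, hyb) {
  key <- switch(element,
                C = paste0("C.", hyb), N = paste0("N.", hyb),
                O = if (hyb == "sp3") "O.sp3" else "O.sp2",
                element)
  if (is.null(.PEOE[[key]])) key <- element
  if (is.null(.PEOE[[key]])) key <- "C.sp3"
  key
}

.hybridization <- function(mol) {
  n <- nrow(mol@atoms)
  maxo <- rep(1L, n); ndbl <- integer(n)
  b <- mol@bonds
  for (k in seq_len(nrow(b))) {
    o <- b$order[k]
    for (v in c(b$i[k], b$j[k])) {
      maxo[v] <- max(maxo[v], o)
      if (o == 2L) ndbl[v] <- ndbl[v] + 1L
    }
  }
  ifelse(maxo == 3L | ndbl >= 2L, "sp", ifelse(maxo >= 2L, "sp2", "sp3"))
}

#' Gasteiger-style partial charges
#'
#' Iterative partial equalization of orbital electronegativity (PEOE) with
#' geometric damping, run over heavy atoms plus implicit hydrogens; hydrogen
#' charges are folded back into the bearing heavy atom.
#'
#' @param mol a [MolecularGraph-class].
#' @param iterations damping iterations (default 6).
#' @return Numeric vector of per-heavy-atom partial charges.
#' @export
gasteigerCharges <- function(mol, iterations = 6L) {
  a <- mol@atoms
  n <- nrow(a)
  h <- implicitHydrogens(mol)
  hyb <- .hybridization(mol)
  # expanded atom list: heavy atoms 1..n, then hydrogens
  keys <- vapply(seq_len(n), function(i) .peoeKey(a$element[i], hyb[i]), character(1))
  owner <- integer(0)
  edges <- cbind(mol@bonds$i, mol@bonds$j)
  for (i in seq_len(n)) {
    if (h[i] > 0L) {
      hidx <- n + length(owner) + seq_len(h[i])
      keys <- c(keys, rep("H", h[i]))
      owner <- c(owner, rep(i, h[i]))
      edges <- rbind(edges, cbind(i, hidx))
    }
  }
  N <- length(keys)
  par <- t(vapply(keys, function(k) .PEOE[[k]], numeric(3)))
  q <- c(as.numeric(a$charge), rep(0, N - n))
  chiPlus <- rowSums(par)          # chi at q = +1
  chiPlus[keys == "H"] <- 20.02    # Gasteiger's hydrogen convention
  if (nrow(edges)) for (it in seq_len(iterations)) {
    damp <- 0.5^it
    chi <- par[, 1] + par[, 2] * q + par[, 3] * q * q
    dq <- numeric(N)
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      if (chi[i] == chi[j]) next
      lo <- if (chi[i] < chi[j]) i else j
      t <- (chi[j] - chi[i]) / chiPlus[lo] * damp
      dq[i] <- dq[i] + t
      dq[j] <- dq[j] - t
    }
    q <- q + dq
  }
  qh <- q[seq_len(n)]
  if (N > n) for (k in seq_len(N - n)) qh[owner[k]] <- qh[owner[k]] + q[n + k]
  qh
}

# coarse additive logP atom contributions (scheme "coarseXLogP-1");
# implicit hydrogens contribute through their heavy atom
.logpContrib <- function(mol) {
  a <- mol@atoms
  n <- nrow(a)
  h <- implicitHydrogens(mol)
  b <- mol@bonds
  nbrs <- vector("list", n); nbro <- vector("list", n)
  for (k in seq_len(nrow(b))) {
    nbrs[[b$i[k]]] <- c(nbrs[[b$i[k]]], b$j[k]); nbro[[b$i[k]]] <- c(nbro[[b$i[k]]], b$order[k])
    nbrs[[b$j[k]]] <- c(nbrs[[b$j[k]]], b$i[k]); nbro[[b$j[k]]] <- c(nbro[[b$j[k]]], b$order[k])
  }
  vapply(seq_len(n), function(i) {
    e <- a$element[i]; nb <- nbrs[[i]]; no <- nbro[[i]]
    base <- switch(e,
      C = if (a$aromatic[i]) 0.29
          else if (any(a$element[nb] %in% c("N", "O"))) -0.05 else 0.14,
      N = if (a$aromatic[i]) -0.49
          else if (any(.isCarbonylC(mol, nb, nbrs, nbro))) -0.66 else -0.60,
      O = if (a$aromatic[i]) -0.03
          else if (any(no == 2L)) -0.20
          else if (h[i] >= 1L) -0.17 else -0.24,
      S = 0.25, P = -0.50, F = 0.22, Cl = 0.65, Br = 0.86, I = 1.12,
      B = 0.18, Si = 0.30, 0)
    if (a$charge[i] != 0L) base <- base - 1.0
    hC <- if (e == "C") 0.12 else -0.23
    base + hC * h[i]
  }, numeric(1))
}

.isCarbonylC <- function(mol, idx, nbrs, nbro) {
  el <- mol@atoms$element
  vapply(idx, function(i)
    el[i] == "C" && any(nbro[[i]] == 2L & el[nbrs[[i]]] == "O"), logical(1))
}

#' Burden-matrix eigenvalue descriptors (24 values)
#'
#' For each weighting scheme (electronegativity \code{EN}, partial charge
#' \code{Q}, logP contribution \code{LP}) the 4 smallest then 4 largest
#' eigenvalues of the Burden matrix, ascending within each block. Molecules
#' with fewer than 4 atoms pad with the clamped extreme eigenvalue.
#'
#' @param mol a connected [MolecularGraph-class] with at least one atom.
#' @return Named numeric vector of length 24
#'   (\code{BN_EN_lo1..4, BN_EN_hi1..4, BN_Q_..., BN_LP_...}).
#' @export
burdenDescriptors <- function(mol) {
  n <- nrow(mol@atoms)
  if (n == 0L) stop("empty molecule")
  deg <- integer(n)
  b <- mol@bonds
  base <- matrix(0.001, n, n)
  diag(base) <- 0
  if (nrow(b)) {
    deg <- tabulate(c(b$i, b$j), n)
    ov <- ifelse(b$order == 4L, 1.5, as.numeric(b$order))
    for (k in seq_len(nrow(b))) {
      v <- 0.1 * ov[k]
      if (deg[b$i[k]] == 1L || deg[b$j[k]] == 1L) v <- v + 0.01
      base[b$i[k], b$j[k]] <- v
      base[b$j[k], b$i[k]] <- v
    }
  }
  weights <- list(
    EN = .ELEMENTS[mol@atoms$element, "en"],
    Q  = gasteigerCharges(mol),
    LP = .logpContrib(mol))
  out <- numeric(0)
  for (w in names(weights)) {
    m <- base
    diag(m) <- weights[[w]]
    ev <- sort(eigen(m, symmetric = TRUE, only.values = TRUE)$values)
    lo <- ev[pmin(1:4, n)]
    hi <- ev[pmax(n - 3:0, 1)]
    out <- c(out, setNames(c(lo, hi),
                           paste0("BN_", w, "_", c(paste0("lo", 1:4), paste0("hi", 1:4)))))
  }
  out
}
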