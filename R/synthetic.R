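# Synthetic bioassay corpora with planted structure: a ring-and-linker
# molecular grammar (the heterocycle families typical of screening
# libraries: benzenes, pyridines, furans, quinolines and relatives), planted
# scaffolds occurring at elevated frequency among actives, PubChem-style
# integer activity scores, and counter-screen flags removing a configured
# majority of scored actives.

.GRAMMAR_RINGS <- c(
  benzene     = "c1ccccc1",
  pyridine    = "c1ccncc1",
  pyrimidine  = "c1cncnc1",
  pyrrole     = "c1cc[nH]c1",
  furan       = "c1ccoc1",
  thiophene   = "c1ccsc1",
  imidazole   = "c1nc[nH]c1",
  cyclohexane = "C1CCCCC1",
  piperidine  = "C1CCNCC1",
  quinoline   = "c1ccc2ncccc2c1"
)

# linkers: SMILES, attachment atom for each side (same atom allowed)
.GRAMMAR_LINKERS <- list(
  direct    = NULL,
  methylene = list(smiles = "C", a1 = 1L, a2 = 1L),
  ethylene  = list(smiles = "CC", a1 = 1L, a2 = 2L),
  ether     = list(smiles = "O", a1 = 1L, a2 = 1L),
  amine     = list(smiles = "N", a1 = 1L, a2 = 1L),
  carbonyl  = list(smiles = "C=O", a1 = 1L, a2 = 1L),
  vinylene  = list(smiles = "C=C", a1 = 1L, a2 = 2L),
  oxymethyl = list(smiles = "CO", a1 = 1L, a2 = 2L)
)

.GRAMMAR_SUBSTITUENTS <- list(
  methyl   = list(smiles = "C", at = 1L),
  hydroxyl = list(smiles = "O", at = 1L),
  amino    = list(smiles = "N", at = 1L),
  fluoro   = list(smiles = "F", at = 1L),
  chloro   = list(smiles = "Cl", at = 1L),
  methoxy  = list(smiles = "OC", at = 1L)
)

.grammarCache <- new.env(parent = emptyenv())
.grammarMol <- function(smiles) {
  hit <- .grammarCache[[smiles]]
  if (is.null(hit)) {
    hit <- parseSmiles(smiles)
    .grammarCache[[smiles]] <- hit
  }
  hit
}

# atoms able to accept one more single bond (an implicit H to give up)
.attachSites <- function(mol) which(implicitHydrogens(mol) >= 1L)

# join two molecules with a single bond between atomA (in a) and atomB (in b),
# consuming one hydrogen on each side
.joinMols <- function(a, atomA, b, atomB) {
  na <- nrow(a@atoms)
  atoms <- rbind(a@atoms, b@atoms)
  bonds <- data.frame(i = c(a@bonds$i, b@bonds$i + na, atomA),
                      j = c(a@bonds$j, b@bonds$j + na, atomB + na),
                      order = c(a@bonds$order, b@bonds$order, 1L))
  for (at in c(atomA, atomB + na))
    if (!is.na(atoms$hcount[at])) atoms$hcount[at] <- atoms$hcount[at] - 1L
  # inputs are valid by construction; skip the validity pass (hot path)
  out <- a
  attributes(atoms)$row.names <- seq_len(nrow(atoms))
  out@atoms <- atoms
  out@bonds <- bonds
  out@name <- ""
  out
}

#' Generate a random ring-and-linker scaffold
#'
#' Joins heterocyclic / carbocyclic ring units (benzene, pyridine,
#' pyrimidine, pyrrole, furan, thiophene, imidazole, cyclohexane, piperidine,
#' quinoline) through short linkers (direct bond, methylene, ethylene, ether,
#' amine, carbonyl, vinylene, oxymethylene) at random valence-legal positions
#' until the scaffold reaches \code{min_atoms} heavy atoms.
#'
#' @param seed integer seed (fixed seed, identical scaffold).
#' @param min_atoms minimum heavy-atom count (default 10, >= 3).
#' @return A connected [MolecularGraph-class].
#' @export
generateScaffold <- function(seed, min_atoms = 10L) {
  stopifnot(min_atoms >= 3L)
  rng <- .seededRNG(seed)
  .withSeed(rng, .generateScaffoldRNG(min_atoms))
}

# grammar draw under the *current* RNG state (internal)
.generateScaffoldRNG <- function(min_atoms = 10L) {
  mol <- .grammarMol(sample(.GRAMMAR_RINGS, 1L))
  while (nrow(mol@atoms) < min_atoms) {
    ring <- .grammarMol(sample(.GRAMMAR_RINGS, 1L))
    linker <- .GRAMMAR_LINKERS[[sample(length(.GRAMMAR_LINKERS), 1L)]]
    siteA <- sample(.attachSites(mol), 1L)
    siteB <- sample(.attachSites(ring), 1L)
    if (is.null(linker)) {
      mol <- .joinMols(mol, siteA, ring, siteB)
    } else {
      lk <- .grammarMol(linker$smiles)
      tmp <- .joinMols(mol, siteA, lk, linker$a1)
      mol <- .joinMols(tmp, nrow(mol@atoms) + linker$a2, ring, siteB)
    }
  }
  mol
}

#' Decorate a scaffold with small substituents
#'
#' Adds 0 to \code{max_substituents} small groups (methyl, hydroxyl, amino,
#' fluoro, chloro, methoxy) at random valence-legal positions. The scaffold
#' always remains a substructure of the product.
#'
#' @param scaffold a valid [MolecularGraph-class].
#' @param seed integer seed.
#' @param max_substituents maximum number of substituents (default 3).
#' @return A [MolecularGraph-class]. If no valence-legal site exists the
#'   scaffold is returned unchanged with a warning.
#' @export
decorateMolecule <- function(scaffold, seed, max_substituents = 3L) {
  rng <- .seededRNG(seed)
  .withSeed(rng, .decorateRNG(scaffold, max_substituents))
}

.decorateRNG <- function(scaffold, max_substituents = 3L) {
  k <- sample(0:max_substituents, 1L)
  if (k == 0L) return(scaffold)
  mol <- scaffold
  placed <- 0L
  for (t in seq_len(k)) {
    sites <- .attachSites(mol)
    sites <- sites[sites <= nrow(scaffold@atoms)]  # decorate the core only
    if (!length(sites)) break
    sub <- .GRAMMAR_SUBSTITUENTS[[sample(length(.GRAMMAR_SUBSTITUENTS), 1L)]]
    mol <- .joinMols(mol, sample(sites, 1L), .grammarMol(sub$smiles), sub$at)
    placed <- placed + 1L
  }
  if (placed == 0L && k > 0L && !length(.attachSites(scaffold)))
    warning("no valence-legal substitution site; scaffold returned unchanged")
  mol
}

#' Configuration for a synthetic bioassay
#'
#' Defaults emulate the corpus shape of a heavily imbalanced reporter-gene
#' screen: ~2.4\% scored actives, integer activity scores (actives uniform on
#' 40-100, inactives 0), a counter-screen flagging ~73\% of scored actives
#' as artifacts, and planted scaffolds at 10\% frequency among actives vs
#' 0.1\% among inactives.
#'
#' Background (non-planted) molecules in both classes are decorated draws
#' from a per-assay pool of \code{background_pool_size} background scaffolds,
#' so every background chemotype is *common* (a few percent of either
#' library): chance double-hits among the few hundred actives then never
#' look significantly enriched. Planted scaffolds are required to be
#' structurally distinct - pairwise and against the background pool - at the
#' default merge threshold (MCS < 10 heavy atoms), which makes the planted
#' signal identifiable.
#'
#' @param n_actives number of scored-active compounds (default 500).
#' @param n_inactives number of inactive compounds (default 20000).
#' @param planted data.frame with columns \code{smiles},
#'   \code{freq_active}, \code{freq_inactive}; by default 3 mutually
#'   dissimilar scaffolds drawn from the grammar at frequencies 0.10 / 0.001.
#' @param counterscreen_fraction fraction of scored actives flagged as
#'   counter-screen artifacts (default 0.731, mirroring a counter-screen
#'   removing ~73\% of scored actives).
#' @param background_pool_size number of distinct background scaffolds
#'   (default 25).
#' @param max_substituents decorations per generated molecule (default 2).
#' @param effects data.frame of planted descriptor effects: columns
#'   \code{column} (descriptor column name), \code{p_active},
#'   \code{p_inactive}. Default: 10 fingerprint bits at 0.80 / 0.20.
#' @param seed integer master seed.
#' @return A list of class \code{"SyntheticAssayConfig"}.
#' @export
syntheticAssayConfig <- function(n_actives = 500L, n_inactives = 20000L,
                                 planted = NULL,
                                 counterscreen_fraction = 0.731,
                                 background_pool_size = 25L,
                                 max_substituents = 2L,
                                 effects = NULL, seed = 1L) {
  stopifnot(n_inactives >= n_actives,
            counterscreen_fraction >= 0, counterscreen_fraction <= 1,
            background_pool_size >= 1L)
  if (is.null(planted)) {
    planted <- data.frame(
      smiles = .distinctScaffolds(3L, seed = seed, min_atoms = 12L,
                                  dissimilar_below = 10L),
      freq_active = 0.10, freq_inactive = 0.001, stringsAsFactors = FALSE)
  }
  if (sum(planted$freq_active) > 1 || sum(planted$freq_inactive) > 1)
    stop("planted scaffold frequencies must sum to at most 1 per class")
  if (any(planted$freq_active <= planted$freq_inactive))
    stop("planted enriched scaffolds need freq_active > freq_inactive")
  if (is.null(effects)) {
    effects <- data.frame(
      column = fingerprintColumnNames()[seq(10, 100, by = 10)],
      p_active = 0.80, p_inactive = 0.20, stringsAsFactors = FALSE)
  }
  structure(list(n_actives = as.integer(n_actives),
                 n_inactives = as.integer(n_inactives),
                 planted = planted,
                 counterscreen_fraction = counterscreen_fraction,
                 background_pool_size = as.integer(background_pool_size),
                 max_substituents = as.integer(max_substituents),
                 effects = effects, seed = as.integer(seed)),
            class = "SyntheticAssayConfig")
}

# Draw scaffolds from the grammar until n distinct ones are found. Candidates
# must share an MCS below `dissimilar_below` heavy atoms with every scaffold
# in `against` (and, when self_dissimilar, with each other); duplicates are
# always rejected.
.distinctScaffolds <- function(n, seed, min_atoms = 12L, dissimilar_below = 10L,
                               against = list(), self_dissimilar = TRUE,
                               max_tries = 600L) {
  rng <- .seededRNG(seed)
  out <- list()
  codes <- character()
  tries <- 0L
  dissim <- function(cand, o) {
    is.null(mcs(cand, o, min_atoms = dissimilar_below)) &&
      !isSubstructure(cand, o) && !isSubstructure(o, cand)
  }
  while (length(out) < n && tries < max_tries) {
    tries <- tries + 1L
    cand <- .withSeed(rng, .generateScaffoldRNG(min_atoms = min_atoms))
    if (canonicalCode(cand) %in% codes) next
    ok <- all(vapply(against, dissim, logical(1), cand = cand))
    if (ok && self_dissimilar && length(out))
      ok <- all(vapply(out, dissim, logical(1), cand = cand))
    if (ok) {
      out[[length(out) + 1L]] <- cand
      codes <- c(codes, canonicalCode(cand))
    }
  }
  if (length(out) < n) stop("could not draw ", n, " mutually dissimilar scaffolds")
  vapply(out, molToSmiles, character(1))
}

#' Generate a synthetic bioassay corpus
#'
#' Each active carries planted scaffold k with probability
#' \code{freq_active[k]} (multinomial assignment), decorated with random
#' substituents; likewise for inactives at \code{freq_inactive}; remaining
#' molecules are decorated random grammar scaffolds. Scores: actives uniform
#' integers on 40-100, inactives 0. A configured fraction of actives is
#' flagged as counter-screen hits, independently of scaffold membership.
#'
#' @param config a [syntheticAssayConfig()].
#' @return List: \code{library} ([CompoundLibrary-class]), \code{scores}
#'   (named integer vector), \code{counterscreen} (character id vector),
#'   \code{truth} (data.frame: id, class, planted scaffold index, 0 = none).
#' @export
generateAssay <- function(config) {
  stopifnot(inherits(config, "SyntheticAssayConfig"))
  plantedMols <- lapply(config$planted$smiles, parseSmiles)
  pool <- lapply(
    .distinctScaffolds(config$background_pool_size, seed = config$seed + 31L,
                       min_atoms = 10L, dissimilar_below = 10L,
                       against = plantedMols, self_dissimilar = FALSE),
    parseSmiles)
  rng <- .seededRNG(config$seed)
  .withSeed(rng, {
    nA <- config$n_actives; nI <- config$n_inactives
    drawClass <- function(n, freqs) {
      # planted index per molecule; 0 = random background
      sample(c(seq_along(freqs), 0L), n, replace = TRUE,
             prob = c(freqs, 1 - sum(freqs)))
    }
    mkMol <- function(assign_idx) {
      core <- if (assign_idx > 0L) plantedMols[[assign_idx]]
              else pool[[sample(length(pool), 1L)]]
      .decorateRNG(core, max_substituents = config$max_substituents)
    }
    aAssign <- drawClass(nA, config$planted$freq_active)
    iAssign <- drawClass(nI, config$planted$freq_inactive)
    ids <- c(sprintf("ACT%05d", seq_len(nA)), sprintf("INA%05d", seq_len(nI)))
    mols <- vector("list", nA + nI)
    for (k in seq_len(nA)) mols[[k]] <- mkMol(aAssign[k])
    for (k in seq_len(nI)) mols[[nA + k]] <- mkMol(iAssign[k])
    for (k in seq_along(mols)) mols[[k]]@name <- ids[k]
    scores <- c(sample(40:100, nA, replace = TRUE), rep(0L, nI))
    names(scores) <- ids
    flags <- ids[seq_len(nA)][runif(nA) < config$counterscreen_fraction]
    truth <- data.frame(id = ids,
                        class = rep(c("active", "inactive"), c(nA, nI)),
                        planted = c(aAssign, iAssign),
                        stringsAsFactors = FALSE)
    list(library = CompoundLibrary(mols, ids = ids),
         scores = scores, counterscreen = flags, truth = truth)
  })
}

#' Simulate a descriptor matrix with planted bit effects
#'
#' Bernoulli fingerprint-bit matrix over the full 179-column layout:
#' configured informative columns use class-conditional probabilities
#' \code{p_active} / \code{p_inactive}; all other binary columns are noise at
#' rate \code{noise_rate} in both classes; the 32 continuous columns are
#' standard normal in both classes (uninformative).
#'
#' @param config a [syntheticAssayConfig()] (uses \code{effects},
#'   \code{n_actives}, \code{n_inactives}, \code{seed}).
#' @param noise_rate background bit rate (default 0.3).
#' @return List: \code{x} ([DescriptorMatrix-class]), \code{labels}.
#' @export
simulateDescriptors <- function(config, noise_rate = 0.3) {
  stopifnot(inherits(config, "SyntheticAssayConfig"))
  rng <- .seededRNG(config$seed + 7L)
  .withSeed(rng, {
    nA <- config$n_actives; nI <- config$n_inactives
    n <- nA + nI
    cols <- descriptorColumnNames()
    labels <- rep(c("active", "inactive"), c(nA, nI))
    x <- matrix(0, n, length(cols), dimnames = list(
      c(sprintf("ACT%05d", seq_len(nA)), sprintf("INA%05d", seq_len(nI))), cols))
    binary <- c(rep(TRUE, 147L), rep(FALSE, 32L))
    for (jc in which(binary)) x[, jc] <- rbinom(n, 1L, noise_rate)
    for (r in seq_len(nrow(config$effects))) {
      jc <- config$effects$column[r]
      p <- ifelse(labels == "active", config$effects$p_active[r],
                  config$effects$p_inactive[r])
      x[, jc] <- rbinom(n, 1L, p)
    }
    x[, !binary] <- rnorm(n * sum(!binary))
    list(x = descriptorMatrix(x, binary = binary,
                              metadata = list(simulated = TRUE)),
         labels = labels)
  })
}
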