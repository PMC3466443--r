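# LibMCS-style hierarchical scaffold clustering. Level 1 holds the input
# molecules as singleton leaves. At each level the pair of clusters whose
# representatives share the largest MCS (>= min_mcs_atoms heavy atoms) is
# merged greedily, each cluster merging at most once per level; the merged
# cluster's representative is that MCS. Unmerged clusters carry over. Ties
# are broken by smaller combined member count, then by the lexicographic
# order of the representatives' canonical codes, so the build is
# deterministic for a given input order.

#' Hierarchical MCS clustering of a compound library
#'
#' @param library a [CompoundLibrary-class] (typically curated actives).
#' @param min_mcs_atoms minimum heavy-atom MCS size allowing a merge
#'   (default 10; leaves are exempt).
#' @param max_levels maximum hierarchy depth (default 6).
#' @param exact_atoms,node_budget passed to [mcs()].
#' @return A [ScaffoldHierarchy-class].
#' @export
hierarchicalMcsCluster <- function(library, min_mcs_atoms = 10L, max_levels = 6L,
                                   exact_atoms = 40L, node_budget = 2e6) {
  stopifnot(length(library) > 0L)
  library <- standardizeLibrary(library)
  clusters <- lapply(seq_along(library@ids), function(k) {
    list(level = 1L, scaffold = library@mols[[k]], members = library@ids[k],
         children = integer(), code = canonicalCode(library@mols[[k]]),
         top = FALSE)
  })
  current <- seq_along(clusters)
  cache <- new.env(parent = emptyenv())  # sorted code pair -> MCS size
  pairSize <- function(ci, cj) {
    key <- paste(sort(c(clusters[[ci]]$code, clusters[[cj]]$code)), collapse = "\r")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    m <- mcs(clusters[[ci]]$scaffold, clusters[[cj]]$scaffold,
             min_atoms = min_mcs_atoms, exact_atoms = exact_atoms,
             node_budget = node_budget)
    size <- if (is.null(m)) 0L else attr(m, "size")
    cache[[key]] <- size
    size
  }
  levels <- 1L
  for (lev in seq.int(2L, length.out = max(0L, max_levels - 1L))) {
    nc <- length(current)
    if (nc < 2L) break
    # candidate merge pairs at this level
    cand <- list()
    for (ii in seq_len(nc - 1L)) for (jj in seq.int(ii + 1L, nc)) {
      s <- pairSize(current[ii], current[jj])
      if (s >= min_mcs_atoms)
        cand[[length(cand) + 1L]] <- c(ii, jj, s)
    }
    if (!length(cand)) break
    cand <- do.call(rbind, cand)
    msize <- vapply(current, function(ci) length(clusters[[ci]]$members), integer(1))
    combined <- msize[cand[, 1]] + msize[cand[, 2]]
    codekey <- vapply(seq_len(nrow(cand)), function(r) {
      paste(sort(c(clusters[[current[cand[r, 1]]]]$code,
                   clusters[[current[cand[r, 2]]]]$code)), collapse = "\r")
    }, character(1))
    ord <- order(-cand[, 3], combined, codekey)
    cand <- cand[ord, , drop = FALSE]
    mergedFlag <- logical(nc)
    newIdx <- integer()
    for (r in seq_len(nrow(cand))) {
      ii <- cand[r, 1]; jj <- cand[r, 2]
      if (mergedFlag[ii] || mergedFlag[jj]) next
      ci <- current[ii]; cj <- current[jj]
      rep <- mcs(clusters[[ci]]$scaffold, clusters[[cj]]$scaffold,
                 min_atoms = min_mcs_atoms, exact_atoms = exact_atoms,
                 node_budget = node_budget)
      if (is.null(rep)) next  # approximate searches may disagree; skip
      clusters[[length(clusters) + 1L]] <- list(
        level = lev, scaffold = rep,
        members = c(clusters[[ci]]$members, clusters[[cj]]$members),
        children = c(ci, cj), code = canonicalCode(rep), top = FALSE)
      newIdx <- c(newIdx, length(clusters))
      mergedFlag[c(ii, jj)] <- TRUE
    }
    if (!length(newIdx)) break
    levels <- lev
    current <- c(newIdx, current[!mergedFlag])
  }
  for (ci in current) clusters[[ci]]$top <- TRUE
  new("ScaffoldHierarchy", clusters = clusters, levels = levels,
      min_mcs_atoms = as.integer(min_mcs_atoms))
}

setMethod("show", "ScaffoldHierarchy", function(object) {
  top <- vapply(object@clusters, `[[`, logical(1), "top")
  cat(sprintf("ScaffoldHierarchy: %d cluster(s) over %d level(s); %d top-level (min MCS %d atoms)\n",
              length(object@clusters), object@levels, sum(top), object@min_mcs_atoms))
})

#' Top-level clusters of a scaffold hierarchy
#'
#' @param hierarchy a [ScaffoldHierarchy-class].
#' @param drop_singletons remove single-member clusters (default TRUE), as
#'   singleton "scaffolds" are whole molecules, not shared cores.
#' @return Data.frame with columns \code{scaffold_id}, \code{level},
#'   \code{n_members}, \code{scaffold_smiles}, \code{members} (list column);
#'   scaffold graphs attached as \code{attr(, "scaffolds")}.
#' @export
topLevelClusters <- function(hierarchy, drop_singletons = TRUE) {
  idx <- which(vapply(hierarchy@clusters, `[[`, logical(1), "top"))
  n <- vapply(idx, function(i) length(hierarchy@clusters[[i]]$members), integer(1))
  if (drop_singletons) {
    message(sum(n == 1L), " singleton cluster(s) removed of ", length(idx), " top-level")
    idx <- idx[n > 1L]; n <- n[n > 1L]
  }
  scaffolds <- lapply(idx, function(i) hierarchy@clusters[[i]]$scaffold)
  out <- data.frame(
    scaffold_id = sprintf("S%d", seq_along(idx)),
    level = vapply(idx, function(i) hierarchy@clusters[[i]]$level, integer(1)),
    n_members = n,
    scaffold_smiles = vapply(scaffolds, function(s)
      if (nrow(s@atoms)) molToSmiles(s) else "", character(1)),
    stringsAsFactors = FALSE)
  out$members <- lapply(idx, function(i) hierarchy@clusters[[i]]$members)
  attr(out, "scaffolds") <- scaffolds
  out
}

#' Which library molecules contain a scaffold
#'
#' @param scaffold a non-empty [MolecularGraph-class].
#' @param library a [CompoundLibrary-class].
#' @return Logical vector over the library (each molecule counted once).
#' @export
matchesScaffold <- function(scaffold, library) {
  stopifnot(nrow(scaffold@atoms) > 0L)
  as.logical(.cpp_match_library(.molPack(scaffold), .packLibrary(library@mols)))
}

#' Count scaffold occurrences in a library
#'
#' @inheritParams matchesScaffold
#' @return Integer count of molecules containing the scaffold.
#' @export
countOccurrences <- function(scaffold, library) sum(matchesScaffold(scaffold, library))
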