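# Scaffold enrichment statistics: Pearson chi-square (no continuity
# correction, df = 1) on the 2x2 occurrence table, and the enrichment factor
# EF = (a / N_act) / (c / N_inact).

#' Chi-square enrichment test for one scaffold
#'
#' Tests whether a scaffold occurs more often among actives than inactives:
#' Pearson chi-square without Yates continuity correction on the table
#' \code{rbind(c(a, N_act - a), c(c, N_inact - c))}. The enrichment factor is
#' the ratio of occurrence frequencies; with \code{c = 0} it is flagged
#' infinite.
#'
#' @param a scaffold occurrences among actives.
#' @param c_inact scaffold occurrences among inactives.
#' @param N_act,N_inact library sizes.
#' @param scaffold_id optional label.
#' @return One-row data.frame: \code{scaffold_id, a, c, N_act, N_inact,
#'   freq_active, chi_square, p_value, enrichment_factor}.
#' @examples
#' enrichmentTest(19, 86, 883, 301747)   # chi-square ~1144.4, EF ~75.5
#' @export
enrichmentTest <- function(a, c_inact, N_act, N_inact, scaffold_id = NA_character_) {
  a <- as.numeric(a); cc <- as.numeric(c_inact)
  if (a < 0 || a > N_act || cc < 0 || cc > N_inact)
    stop("invalid counts: need 0 <= a <= N_act and 0 <= c <= N_inact")
  if (a == 0 && cc == 0) stop("scaffold occurs nowhere; the test is undefined")
  tab <- rbind(c(a, N_act - a), c(cc, N_inact - cc))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  ef <- if (cc > 0) (a / N_act) / (cc / N_inact) else Inf
  data.frame(scaffold_id = scaffold_id, a = a, c = cc,
             N_act = N_act, N_inact = N_inact,
             freq_active = a / N_act,
             chi_square = unname(ct$statistic), p_value = unname(ct$p.value),
             enrichment_factor = ef, stringsAsFactors = FALSE)
}

#' Enrichment table for a set of scaffolds
#'
#' Counts each scaffold in the active and inactive libraries (each molecule
#' at most once) and runs [enrichmentTest()].
#'
#' @param scaffolds list of [MolecularGraph-class] scaffolds, or the
#'   data.frame from [topLevelClusters()] (its attached scaffold graphs are
#'   used).
#' @param actives,inactives [CompoundLibrary-class] objects.
#' @return Data.frame, one row per scaffold, with a \code{scaffold_smiles}
#'   column.
#' @export
scaffoldEnrichment <- function(scaffolds, actives, inactives) {
  ids <- NULL
  if (is.data.frame(scaffolds)) {
    ids <- scaffolds$scaffold_id
    scaffolds <- attr(scaffolds, "scaffolds")
  }
  stopifnot(length(scaffolds) > 0L)
  if (is.null(ids)) ids <- paste0("S", seq_along(scaffolds))
  packedA <- .packLibrary(actives@mols)    # pack each library once
  packedI <- .packLibrary(inactives@mols)
  rows <- lapply(seq_along(scaffolds), function(k) {
    q <- .molPack(scaffolds[[k]])
    r <- enrichmentTest(sum(.cpp_match_library(q, packedA)),
                        sum(.cpp_match_library(q, packedI)),
                        length(actives), length(inactives), scaffold_id = ids[k])
    r$scaffold_smiles <- molToSmiles(scaffolds[[k]])
    r
  })
  out <- do.call(rbind, rows)
  attr(out, "scaffolds") <- scaffolds
  out
}

#' Select significantly enriched scaffolds
#'
#' Keeps scaffolds with active-set frequency strictly above \code{freq_min},
#' p-value strictly below \code{p_max} and enrichment factor strictly above
#' \code{ef_min}; sorted by descending enrichment factor.
#'
#' @param results data.frame from [enrichmentTest()] / [scaffoldEnrichment()].
#' @param freq_min minimum occurrence frequency among actives (default 0.01).
#' @param p_max p-value cutoff (default 0.01).
#' @param ef_min enrichment-factor cutoff (default 2).
#' @return The filtered, EF-sorted data.frame.
#' @export
selectEnriched <- function(results, freq_min = 0.01, p_max = 0.01, ef_min = 2) {
  keep <- results$freq_active > freq_min &
    results$p_value < p_max &
    results$enrichment_factor > ef_min
  out <- results[keep, , drop = FALSE]
  scf <- attr(results, "scaffolds")
  ord <- order(-out$enrichment_factor)
  out <- out[ord, , drop = FALSE]
  if (!is.null(scf)) attr(out, "scaffolds") <- scf[which(keep)][ord]
  rownames(out) <- NULL
  out
}

#' Reference scaffold occurrence counts from the miR-21 bioassay corpus
#'
#' The published occurrence counts of the 14 significantly enriched scaffolds
#' in the curated miR-21 modulator screen (883 actives, 301,747 inactives
#' after counter-screen filtering), for re-deriving their chi-square and
#' enrichment-factor statistics.
#'
#' @return Data.frame with columns \code{scaffold_no}, \code{actives},
#'   \code{inactives}, plus \code{N_act}, \code{N_inact} attributes.
#' @export
mir21ScaffoldCounts <- function() {
  path <- system.file("extdata", "mir21_scaffold_counts.csv",
                      package = "ScaffoldScreen", mustWork = TRUE)
  out <- read.csv(path)
  attr(out, "N_act") <- 883L
  attr(out, "N_inact") <- 301747L
  out
}
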