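# End-to-end pipeline: curate -> featurize -> filter -> split -> tune/train
# -> evaluate -> cluster -> enrich (-> screen). Each stage logs record
# counts; outputs and a resolved-config snapshot land in the run directory.

#' Pipeline configuration
#'
#' @param input either a \code{SyntheticAssayConfig} (the corpus is
#'   generated) or a list with paths \code{sdf} (structures with a score
#'   property), \code{score_property} (SDF field holding the activity score,
#'   default \code{"PUBCHEM_ACTIVITY_SCORE"}) and optionally \code{flags}
#'   (text file of counter-screen hit ids, one per line).
#' @param outdir run directory (created if missing).
#' @param models which classifiers to train: subset of \code{c("nb", "rf")}.
#' @param fp_cap CV false-positive-rate cap for the cost search (default 0.20).
#' @param folds CV folds (default 5).
#' @param test_fraction held-out test proportion (default 0.2).
#' @param min_mcs_atoms MCS merge threshold in heavy atoms (default 10).
#' @param max_levels scaffold hierarchy depth (default 6).
#' @param freq_min,p_max,ef_min enrichment selection thresholds (defaults
#'   0.01, 0.01, 2).
#' @param screen_library optional [CompoundLibrary-class] (or SMILES file
#'   path) to consensus-screen with the trained models.
#' @param seed master seed.
#' @return A list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(input, outdir = tempfile("scaffoldscreen_run_"),
                           models = c("nb", "rf"), fp_cap = 0.20, folds = 5L,
                           test_fraction = 0.2, min_mcs_atoms = 10L,
                           max_levels = 6L, freq_min = 0.01, p_max = 0.01,
                           ef_min = 2, screen_library = NULL, seed = 1L) {
  stopifnot(fp_cap > 0, fp_cap <= 1, test_fraction > 0, test_fraction < 1,
            folds >= 2L, min_mcs_atoms >= 3L, max_levels >= 1L,
            freq_min >= 0, freq_min < 1, p_max > 0, p_max <= 1, ef_min >= 0)
  models <- match.arg(models, c("nb", "rf"), several.ok = TRUE)
  if (!inherits(input, "SyntheticAssayConfig")) {
    stopifnot(is.list(input), !is.null(input$sdf))
    if (!file.exists(input$sdf)) stop("input SDF not found: ", input$sdf)
    if (!is.null(input$flags) && !file.exists(input$flags))
      stop("flags file not found: ", input$flags)
    if (is.null(input$score_property)) input$score_property <- "PUBCHEM_ACTIVITY_SCORE"
  }
  structure(list(input = input, outdir = outdir, models = models,
                 fp_cap = fp_cap, folds = as.integer(folds),
                 test_fraction = test_fraction,
                 min_mcs_atoms = as.integer(min_mcs_atoms),
                 max_levels = as.integer(max_levels), freq_min = freq_min,
                 p_max = p_max, ef_min = ef_min,
                 screen_library = screen_library, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Run the full screening-analysis pipeline
#'
#' @param config a [pipelineConfig()].
#' @return Invisibly, a list with the curated dataset, descriptor matrices,
#'   models, metrics, the scaffold hierarchy and the enrichment tables; all
#'   artifacts are also written under \code{config$outdir}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  snapshot <- config
  snapshot$screen_library <- if (is.null(config$screen_library)) NULL else "supplied"
  if (inherits(config$input, "SyntheticAssayConfig"))
    snapshot$input <- config$input[setdiff(names(config$input), "")]
  jsonlite::write_json(snapshot, file.path(config$outdir, "resolved_config.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)

  # --- stage: load / generate -----------------------------------------------
  if (inherits(config$input, "SyntheticAssayConfig")) {
    assay <- generateAssay(config$input)
    library <- assay$library
    scores <- assay$scores
    flags <- assay$counterscreen
  } else {
    library <- readSDF(config$input$sdf)
    props <- compoundProperties(library)
    if (!config$input$score_property %in% names(props))
      stop("score property '", config$input$score_property, "' missing from SDF")
    scores <- setNames(as.integer(props[[config$input$score_property]]),
                       compoundIds(library))
    flags <- if (!is.null(config$input$flags))
      readLines(config$input$flags, warn = FALSE) else character()
  }
  logf("input: %d compounds, %d counter-screen flag(s)", length(library), length(flags))

  # --- stage: curate ---------------------------------------------------------
  ds <- assayDataset(compoundIds(library), scores)
  ds <- counterscreenFilter(ds, flags)
  modeling <- makeModelingSet(ds)
  logf("curated: %d active / %d inactive records",
       sum(modeling$class == "active"), sum(modeling$class == "inactive"))
  write.csv(modeling, file.path(config$outdir, "curated.csv"), row.names = FALSE)

  # --- stage: featurize + filter --------------------------------------------
  modLib <- library[modeling$id]
  feats <- featurizeLibrary(modLib)
  feats <- filterConstantBits(feats)
  logf("descriptors: %d x %d after constant-bit filtering",
       nrow(feats@values), ncol(feats@values))
  labels <- setNames(modeling$class, modeling$id)[rownames(feats@values)]

  # --- stage: split + train/tune --------------------------------------------
  keep <- data.frame(id = rownames(feats@values), class = labels,
                     stringsAsFactors = FALSE)
  split <- splitTrainTest(keep, test_fraction = config$test_fraction,
                          seed = config$seed)
  logf("split: %d train / %d test", nrow(split$train), nrow(split$test))
  xtr <- feats@values[split$train$id, , drop = FALSE]
  xte <- feats@values[split$test$id, , drop = FALSE]
  binary <- feats@binary

  trainers <- list(
    nb = function(x, lab) trainNaiveBayes(x, lab, binary = binary),
    rf = function(x, lab) trainRandomForest(x, lab, seed = config$seed))
  models <- list(); metrics <- list()
  for (mn in config$models) {
    tuned <- tuneCost(xtr, split$train$class, train = trainers[[mn]],
                      fp_cap = config$fp_cap, k = config$folds,
                      seed = config$seed)
    model <- trainers[[mn]](xtr, split$train$class)
    pte <- predictProb(model, xte)
    pred <- costSensitivePredict(pte, tuned$cost)
    cm <- confusionCounts(split$test$class, pred)
    met <- suppressWarnings(classificationMetrics(cm))
    roc <- rocAuc(split$test$class, pte)
    cvrow <- tuned$trace[tuned$trace$cost == tuned$cost@cost_fn, ]
    metrics[[mn]] <- list(cost_fn = tuned$cost@cost_fn,
                          cv = as.list(cvrow),
                          test = c(as.list(met), auc = roc$auc),
                          confusion = as.list(cm))
    models[[mn]] <- list(model = model, cost = tuned$cost, trace = tuned$trace)
    logf("%s: cost %g, CV FPR %.3f / TPR %.3f; test AUC %.3f", toupper(mn),
         tuned$cost@cost_fn, cvrow$FPR, cvrow$TPR, roc$auc)
    utils::write.csv(tuned$trace,
                     file.path(config$outdir, paste0("cost_trace_", mn, ".csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(metrics, file.path(config$outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- stage: cluster actives + enrichment ----------------------------------
  activeIds <- modeling$id[modeling$class == "active"]
  inactiveIds <- modeling$id[modeling$class == "inactive"]
  actLib <- library[activeIds]
  inactLib <- library[inactiveIds]
  hierarchy <- hierarchicalMcsCluster(actLib,
                                      min_mcs_atoms = config$min_mcs_atoms,
                                      max_levels = config$max_levels)
  clusters <- topLevelClusters(hierarchy)
  logf("clustering: %d cluster(s) over %d level(s); %d multi-member top-level",
       length(hierarchy@clusters), hierarchy@levels, nrow(clusters))
  enrichment <- NULL
  selected <- NULL
  if (nrow(clusters)) {
    enrichment <- scaffoldEnrichment(clusters, actLib, inactLib)
    selected <- selectEnriched(enrichment, freq_min = config$freq_min,
                               p_max = config$p_max, ef_min = config$ef_min)
    logf("enrichment: %d scaffold(s) tested, %d selected",
         nrow(enrichment), nrow(selected))
    write.csv(enrichment[order(-enrichment$enrichment_factor), ],
              file.path(config$outdir, "enrichment.csv"), row.names = FALSE)
    write.csv(selected, file.path(config$outdir, "enriched_selected.csv"),
              row.names = FALSE)
    writeLines(paste(clusters$scaffold_smiles, clusters$scaffold_id,
                     clusters$level, clusters$n_members),
               file.path(config$outdir, "scaffolds.smi"))
  } else {
    logf("enrichment: no multi-member clusters; skipped")
  }

  # --- stage: consensus screen (optional) ------------------------------------
  screen <- NULL
  if (!is.null(config$screen_library)) {
    screenLib <- if (is.character(config$screen_library))
      readSmilesFile(config$screen_library) else config$screen_library
    sfeat <- featurizeLibrary(screenLib)
    x <- sfeat@values[, colnames(feats@values), drop = FALSE]
    screen <- consensusScreen(lapply(models, `[[`, "model"), x,
                              cost = models[[config$models[1]]]$cost)
    logf("screen: %d consensus hit(s) of %d compounds",
         length(screen$consensus), length(screenLib))
    jsonlite::write_json(screen, file.path(config$outdir, "screen.json"),
                         auto_unbox = TRUE)
  }

  invisible(list(dataset = modeling, descriptors = feats, split = split,
                 models = models, metrics = metrics, hierarchy = hierarchy,
                 clusters = clusters, enrichment = enrichment,
                 selected = selected, screen = screen, outdir = config$outdir))
}
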