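#' Default pipeline configuration
#'
#' A nested list with one element per stage (`simulate`, `deg`, `hubs`,
#' `eigencoord`, `classify`) plus a global `seed`.  Every entry mirrors
#' an argument of the corresponding stage function; unknown keys are
#' rejected by [runPipeline()] before any stage runs.
#'
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    simulate = list(
      nHubs = 3L, anchorGene = "anchor",
      rhoCase = 0.9, rhoControl = 0.1,
      meanShift = 2, nShifted = 3L,
      groupSizes = c(AD = 40L, CON = 40L),
      noiseSd = 1, extraGenes = 12L),
    deg = list(lfcThresh = 1.5, pThresh = 0.05, useAdjusted = TRUE),
    hubs = list(minScore = 0.99, topK = 10L,
                nNodes = 30L, plantedDegrees = c(12L, 9L, 7L)),
    eigencoord = list(refGroup = "CON", scope = "within",
                      sdDivisor = "m-1"),
    classify = list(weights = c(RF = 2, SVM = 2, GMM = 1, LM = 1),
                    trainFraction = 0.8, stratified = TRUE)
  )
}

.mergeConfig <- function(defaults, config) {
  for (key in names(config)) {
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", key, "'")
    if (is.list(defaults[[key]]) && is.list(config[[key]])) {
      defaults[[key]] <- .mergeConfig(defaults[[key]], config[[key]])
    } else if (is.atomic(defaults[[key]]) && is.list(config[[key]])) {
      # YAML maps arrive as named lists where defaults hold named vectors
      defaults[[key]] <- unlist(config[[key]])
    } else {
      defaults[[key]] <- config[[key]]
    }
  }
  defaults
}

# yaml drops names of atomic vectors; store them as maps instead
.yamlReady <- function(x) {
  if (is.list(x)) lapply(x, .yamlReady)
  else if (!is.null(names(x))) as.list(x)
  else x
}

#' Run the full synthetic analysis pipeline
#'
#' Orchestrates the stages end to end on simulated data: simulate a
#' two-group expression study and a planted-hub edge list, call DEGs,
#' rank hubs by degree, run the eigen-coordination comparison of the hub
#' module plus anchor gene, and evaluate the soft-voting ensemble
#' classifier on the hub signature.  All stage outputs, the resolved
#' configuration and a short log are written under `outDir`; identical
#' configurations produce identical outputs.
#'
#' @param config nested list overriding parts of
#'   [defaultPipelineConfig()], or a path to a YAML file with the same
#'   structure.  Unknown keys are rejected before any stage runs.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results
#'   (`expression`, `degs`, `edges`, `hubs`, `coordination`,
#'   `classification`) and `outDir`.
#' @examples
#' \donttest{
#' res <- runPipeline(list(seed = 7), outDir = tempfile("run"))
#' res$classification$auc
#' }
#' @export
runPipeline <- function(config = list(), outDir = "eigencoord_run") {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(defaultPipelineConfig(), config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logLines <- character(0)
  note <- function(...) logLines <<- c(logLines, sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # -- simulate ------------------------------------------------------------
  sim <- cfg$simulate
  hubGenes <- paste0("hub", LETTERS[seq_len(sim$nHubs)])
  shifted <- hubGenes[seq_len(min(sim$nShifted, length(hubGenes)))]
  groups <- names(sim$groupSizes)
  design <- stage("simulate", syntheticDesign(
    modules = stats::setNames(list(c(hubGenes, sim$anchorGene)), "M1"),
    rho = stats::setNames(
      list(c(M1 = sim$rhoCase), c(M1 = sim$rhoControl)), groups),
    meanShift = stats::setNames(rep(sim$meanShift, length(shifted)),
                                shifted),
    shiftGroup = groups[1L],
    groupSizes = sim$groupSizes, noiseSd = sim$noiseSd,
    seed = cfg$seed, extraGenes = sim$extraGenes))
  se <- stage("simulate", simulateExpression(design))
  writeExpressionTSV(se, file.path(outDir, "expression.tsv"),
                     file.path(outDir, "labels.tsv"))
  note("simulate: %d genes x %d samples", nrow(se), ncol(se))

  # -- deg -----------------------------------------------------------------
  degs <- stage("deg", degTable(
    se, caseGroup = groups[1L], controlGroup = groups[2L],
    lfcThresh = cfg$deg$lfcThresh, pThresh = cfg$deg$pThresh,
    useAdjusted = cfg$deg$useAdjusted))
  utils::write.table(degs, file.path(outDir, "deg_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("deg: %d up, %d down of %d genes",
       sum(degs$status == "up"), sum(degs$status == "down"), nrow(degs))

  # -- hubs ----------------------------------------------------------------
  hb <- cfg$hubs
  planted <- stats::setNames(as.integer(hb$plantedDegrees),
                             hubGenes[seq_along(hb$plantedDegrees)])
  edges <- stage("hubs", simulateEdgeList(
    hb$nNodes, planted, seed = cfg$seed))
  retained <- filterEdges(edges, minScore = min(hb$minScore,
                                                max(edges$score)))
  hubs <- stage("hubs", degreeRanking(edges, k = hb$topK))
  utils::write.table(edges, file.path(outDir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hubs, file.path(outDir, "hub_ranking.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("hubs: top hub %s (degree %d)", hubs$node[1L], hubs$degree[1L])

  # -- eigencoord ----------------------------------------------------------
  comp <- stage("eigencoord", coordinationAnalysis(
    se, hubGenes, anchorGene = sim$anchorGene,
    refGroup = cfg$eigencoord$refGroup,
    scope = cfg$eigencoord$scope,
    sdDivisor = cfg$eigencoord$sdDivisor))
  spectra <- comparisonSpectra(comp)
  coordJson <- list(
    groups = names(spectra),
    spectra = lapply(spectra, spectrumValues),
    genes = geneIds(spectra[[1L]]),
    perRankDelta = perRankDelta(comp),
    largestDelta = largestDelta(comp),
    smallestDelta = smallestDelta(comp))
  jsonlite::write_json(coordJson, file.path(outDir, "coordination.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("eigencoord: largest-rank delta %+0.4f", largestDelta(comp))

  # -- classify ------------------------------------------------------------
  cls <- stage("classify", runClassification(
    se, hubGenes, posClass = groups[1L],
    weights = unlist(cfg$classify$weights),
    trainFraction = cfg$classify$trainFraction, seed = cfg$seed,
    stratified = cfg$classify$stratified))
  jsonlite::write_json(
    list(accuracy = cls$accuracy, auc = cls$auc,
         roc = cls$roc, nTest = length(cls$truth)),
    file.path(outDir, "classifier_metrics.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(
    data.frame(sample = rownames(cls$ensemble), cls$ensemble,
               check.names = FALSE),
    file.path(outDir, "ensemble_probabilities.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  note("classify: accuracy %.3f, AUC %.3f", cls$accuracy, cls$auc)

  yaml::write_yaml(.yamlReady(cfg), file.path(outDir, "config.yaml"))
  writeLines(logLines, file.path(outDir, "run.log"))
  invisible(list(expression = se, degs = degs, edges = edges,
                 hubs = hubs, coordination = comp,
                 classification = cls, outDir = outDir))
}
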