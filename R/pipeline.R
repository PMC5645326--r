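#' @include synthetic.R
NULL

.stage <- function(panel, stage, verbose, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("[%s/%s] %s", panel, stage, conditionMessage(e)),
         call. = FALSE))
  if (verbose)
    message(sprintf("[%s] %-12s done in %.2fs", panel, stage,
                    proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full discriminant-PLS pipeline
#'
#' Orchestrates, for each requested panel: ingest (or synthetic
#' generation) -> total-protein normalization -> column z-scoring ->
#' discriminant encoding -> 2-LV NIPALS PLS -> separation rotation ->
#' Monte Carlo subsampled loadings -> tables. When `outputDir` is given,
#' writes per-panel scores and loading-summary tables, a model JSON, a run
#' manifest (seed, configuration fingerprint, redraw counts, package
#' version), and — with `plots = TRUE` — the scores scatter and loading
#' bar charts.
#'
#' @param cytokinePath,phosphoPath delimited input files (see
#'   [readAnalyteTable()]); leave `NULL` to generate synthetic data.
#' @param synthetic generate data instead of reading files; defaults to
#'   `TRUE` exactly when no path is supplied.
#' @param syntheticConfig a [syntheticConfig()]; default uses `seed`.
#' @param panels which panels to analyze.
#' @param targetCondition condition the rotation separates (default
#'   `"hypoxia_bFGF"`).
#' @param nComponents latent variables to fit (default 2).
#' @param normalizeProtein named logical per panel; disable for a phospho
#'   panel already loaded at equal protein per well.
#' @param nIterations,subsampleFraction Monte Carlo settings (defaults
#'   1000 and 0.8); ignored if `mcConfig` is given.
#' @param mcConfig an explicit [MonteCarloConfig-class].
#' @param gridSize rotation search grid (default 3600).
#' @param seed integer seed for generation and subsampling.
#' @param outputDir optional directory for tables/manifest/plots.
#' @param plots also render figures (requires `outputDir`).
#' @param verbose log each stage with timings.
#' @return A list of class `"RunReport"`: per-panel entries each holding
#'   `table`, `normalized`, `design`, `model` ([RotatedModel-class]),
#'   `mc` ([MonteCarloSummary-class]), `scoresTable`, `loadingsTable`,
#'   `theta`, `separationScore`, `redrawCount`; plus `manifest`.
#' @examples
#' rep <- runPipeline(panels = "phospho", nIterations = 50, seed = 3)
#' rep$phospho$model
#' head(rep$phospho$loadingsTable)
#' @export
runPipeline <- function(cytokinePath = NULL, phosphoPath = NULL,
                        synthetic = is.null(cytokinePath) &&
                          is.null(phosphoPath),
                        syntheticConfig = NULL,
                        panels = c("cytokine", "phospho"),
                        targetCondition = "hypoxia_bFGF",
                        nComponents = 2,
                        normalizeProtein = c(cytokine = TRUE, phospho = TRUE),
                        nIterations = 1000, subsampleFraction = 0.8,
                        mcConfig = NULL, gridSize = 3600,
                        seed = 1L, outputDir = NULL, plots = FALSE,
                        verbose = FALSE) {
  panels <- match.arg(panels, several.ok = TRUE)
  paths <- list(cytokine = cytokinePath, phospho = phosphoPath)
  for (pn in panels) {
    hasPath <- !is.null(paths[[pn]])
    if (hasPath == synthetic)
      stop("panel '", pn, "': exactly one of an input path or ",
           "synthetic generation must be selected")
  }
  if (synthetic && is.null(syntheticConfig))
    syntheticConfig <- dplsr::syntheticConfig(seed = seed)
  if (is.null(mcConfig))
    mcConfig <- monteCarloConfig(nIterations = nIterations,
                                 subsampleFraction = subsampleFraction,
                                 seed = seed)
  report <- list()
  for (pn in panels) {
    tab <- .stage(pn, "ingest", verbose, {
      if (synthetic) generatePanel(syntheticConfig, pn)$table
      else readAnalyteTable(paths[[pn]], pn)
    })
    norm <- tab
    if (isTRUE(normalizeProtein[[pn]]))
      norm <- .stage(pn, "normalize", verbose, normalizeTotalProtein(tab))
    nm <- .stage(pn, "zscore", verbose, zscoreColumns(norm))
    design <- .stage(pn, "encode", verbose,
                     encodeDiscriminant(sampleConditions(nm),
                                        targetCondition))
    base <- .stage(pn, "fit", verbose,
                   fitPLS(nm, design, nComponents = nComponents))
    model <- .stage(pn, "rotate", verbose,
                    rotateForSeparation(base, design, gridSize = gridSize))
    mc <- .stage(pn, "montecarlo", verbose,
                 monteCarloLoadings(nm, model, design, mcConfig))
    rs <- rotatedScores(model)
    scoresTable <- data.frame(sample_id = sampleIds(nm),
                              condition = sampleConditions(nm),
                              lv1 = rs[, 1], lv2 = rs[, 2],
                              stringsAsFactors = FALSE)
    report[[pn]] <- list(table = tab, normalized = norm, design = design,
                         model = model, mc = mc,
                         scoresTable = scoresTable,
                         loadingsTable = mcTable(mc),
                         theta = rotationAngle(model),
                         separationScore = separationScore(model),
                         redrawCount = mc@redrawCount)
    if (verbose)
      message(sprintf(
        "[%s] theta = %.1f deg, separation score %.3f, %d redraws",
        pn, report[[pn]]$theta * 180 / pi,
        report[[pn]]$separationScore, report[[pn]]$redrawCount))
  }
  cfgTxt <- paste(utils::capture.output(utils::str(list(
    panels = panels, target = targetCondition, nComponents = nComponents,
    normalizeProtein = normalizeProtein,
    nIterations = mcConfig@nIterations,
    fraction = mcConfig@subsampleFraction, gridSize = gridSize,
    seed = seed, synthetic = synthetic))), collapse = "\n")
  report$manifest <- list(
    seed = as.integer(seed),
    config_hash = fnv1a32(cfgTxt),
    target_condition = targetCondition,
    n_components = as.integer(nComponents),
    n_iterations = mcConfig@nIterations,
    subsample_fraction = mcConfig@subsampleFraction,
    grid_size = as.integer(gridSize),
    synthetic = synthetic,
    panels = panels,
    redraw_counts = lapply(report[panels], `[[`, "redrawCount"),
    version = as.character(utils::packageVersion("dplsr")))
  class(report) <- "RunReport"
  if (!is.null(outputDir)) writeRunReport(report, outputDir, plots = plots)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (seed", x$manifest$seed, ")\n")
  for (pn in x$manifest$panels) {
    cat(sprintf(
      " %s: %d analytes, theta = %.1f deg, separation score %.3f\n",
      pn, nrow(x[[pn]]$loadingsTable), x[[pn]]$theta * 180 / pi,
      x[[pn]]$separationScore))
  }
  invisible(x)
}

#' Write a run report to disk
#'
#' Per panel: `scores_<panel>.csv`, `loadings_<panel>.csv`,
#' `model_<panel>.json`; plus `manifest.json`, and figures when
#' `plots = TRUE`. Files are written only after all panels completed, so
#' a failed run leaves no partial tables.
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param outputDir directory, created if needed.
#' @param plots also call [renderPlots()].
#' @return `outputDir`, invisibly.
#' @export
writeRunReport <- function(report, outputDir, plots = FALSE) {
  stopifnot(inherits(report, "RunReport"))
  if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
  for (pn in report$manifest$panels) {
    r <- report[[pn]]
    utils::write.csv(r$scoresTable,
                     file.path(outputDir, paste0("scores_", pn, ".csv")),
                     row.names = FALSE)
    utils::write.csv(r$loadingsTable,
                     file.path(outputDir, paste0("loadings_", pn, ".csv")),
                     row.names = FALSE)
    writeModelJSON(r$model,
                   file.path(outputDir, paste0("model_", pn, ".json")),
                   conditions = r$scoresTable$condition)
  }
  jsonlite::write_json(report$manifest, file.path(outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (plots) renderPlots(report, outputDir)
  invisible(outputDir)
}
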