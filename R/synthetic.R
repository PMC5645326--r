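#' @include resampling.R
NULL

.studyConditions <- c("normoxia", "normoxia_bFGF", "hypoxia", "hypoxia_bFGF")

#' Default planted effects for a panel
#'
#' Effect maps (analyte -> condition -> effect size, in units of
#' within-condition SD) emulating the reported signaling shifts: for the
#' cytokine panel, G-CSF-, IL-9- and MIP-like analytes elevated under
#' hypoxia+bFGF, an MCP-1-like analyte elevated under hypoxia alone, and
#' two analytes depressed under hypoxia+bFGF; for the phospho panel,
#' phospho-cJun-, Mek1- and Atf2-like analytes elevated and p38- and
#' Jnk-like depressed under hypoxia+bFGF, with a Stat1-like hypoxia-alone
#' correlate. Magnitudes are 2-3 SD. Remaining analytes are null.
#'
#' @param panel `"cytokine"` or `"phospho"`.
#' @return Named list: `analyte -> named numeric (condition -> effect)`.
#' @export
defaultEffects <- function(panel = c("cytokine", "phospho")) {
  panel <- match.arg(panel)
  if (panel == "cytokine") {
    list(
      GCSF_like  = c(hypoxia_bFGF = 3.0),
      IL9_like   = c(hypoxia_bFGF = 2.5),
      MIP2_like  = c(hypoxia_bFGF = 2.0),
      IL12_like  = c(hypoxia_bFGF = -2.0),
      TNFa_like  = c(hypoxia_bFGF = -2.5),
      MCP1_like  = c(hypoxia = 2.5)
    )
  } else {
    list(
      pcJun_like = c(hypoxia_bFGF = 3.0),
      pMek1_like = c(hypoxia_bFGF = 2.5),
      pAtf2_like = c(hypoxia_bFGF = 2.0),
      pp38_like  = c(hypoxia_bFGF = -2.5),
      pJnk_like  = c(hypoxia_bFGF = -2.0),
      pStat1_like = c(hypoxia = 2.5)
    )
  }
}

#' Synthetic experiment configuration
#'
#' Describes the emulated study: four culture conditions (normoxia and 5
#' percent O2 hypoxia, each with and without 10 ng/mL bFGF), 3-4
#' independent cultures per condition (15 samples), 32 cytokine and 8
#' phospho-protein analytes. Each raw measurement is
#' `baselineMean * conditionMultiplier * (totalProtein / referenceProtein)`
#' times multiplicative lognormal noise (or plus additive gaussian noise,
#' clipped at 0): raw analyte abundance scales with each well's total
#' protein, standing in for differential proliferation, which is the
#' confound that total-protein normalization removes. Condition
#' multipliers realize the planted `effects`, stated in units of
#' within-condition SD. Total protein is drawn per sample (lognormal, 10
#' percent CV) around condition-dependent means, higher under hypoxia and
#' hypoxia+bFGF.
#'
#' @param conditions ordered condition labels.
#' @param nPerCondition integer vector, cultures per condition.
#' @param nCytokines,nPhospho panel sizes.
#' @param effects named list per panel (`cytokine`, `phospho`) of effect
#'   maps (see [defaultEffects()]); `NULL` uses the defaults.
#' @param baselineMean baseline raw measurement level (assay units).
#' @param noiseModel `"lognormal"` (default) or `"gaussian"`.
#' @param noiseSd noise scale: sdlog of the lognormal (default 0.25,
#'   roughly 25 percent CV, typical between-culture multiplexed-assay
#'   variability), or relative SD of the gaussian.
#' @param totalProteinMeans named numeric, mean micrograms of total
#'   protein per condition.
#' @param seed integer seed.
#' @return A validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(conditions = .studyConditions,
                            nPerCondition = c(3L, 4L, 4L, 4L),
                            nCytokines = 32L, nPhospho = 8L,
                            effects = NULL,
                            baselineMean = 100,
                            noiseModel = c("lognormal", "gaussian"),
                            noiseSd = 0.25,
                            totalProteinMeans = c(normoxia = 8,
                                                  normoxia_bFGF = 10,
                                                  hypoxia = 12,
                                                  hypoxia_bFGF = 15),
                            seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  if (length(nPerCondition) != length(conditions))
    stop("nPerCondition must have one entry per condition")
  if (any(nPerCondition < 1))
    stop("every condition needs at least one culture")
  if (nCytokines < 1 || nPhospho < 1)
    stop("panel sizes must be >= 1")
  if (noiseSd <= 0) stop("noiseSd must be > 0")
  if (baselineMean <= 0) stop("baselineMean must be > 0")
  if (!all(conditions %in% names(totalProteinMeans)))
    stop("totalProteinMeans must name every condition")
  if (any(totalProteinMeans <= 0))
    stop("totalProteinMeans must be positive")
  if (is.null(effects))
    effects <- list(cytokine = defaultEffects("cytokine"),
                    phospho = defaultEffects("phospho"))
  for (pn in names(effects))
    for (an in names(effects[[pn]]))
      if (!all(names(effects[[pn]][[an]]) %in% conditions))
        stop("effect for '", an, "' names an unknown condition")
  structure(list(conditions = as.character(conditions),
                 nPerCondition = as.integer(nPerCondition),
                 nCytokines = as.integer(nCytokines),
                 nPhospho = as.integer(nPhospho),
                 effects = effects,
                 baselineMean = baselineMean,
                 noiseModel = noiseModel,
                 noiseSd = noiseSd,
                 totalProteinMeans = totalProteinMeans,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Analyte name roster for one panel: planted names first (from the effect
# map, in its order), then numbered nulls up to the panel size.
.panelAnalytes <- function(config, panel) {
  pEff <- config$effects[[panel]]
  pSize <- if (panel == "cytokine") config$nCytokines else config$nPhospho
  planted <- names(pEff)
  if (length(planted) > pSize)
    stop("more planted analytes than panel size for ", panel)
  prefix <- if (panel == "cytokine") "CYT" else "PP"
  nulls <- sprintf("%s%02d_null", prefix,
                   seq_len(pSize - length(planted)))
  c(planted, nulls)
}

#' Generate one synthetic panel
#'
#' Draws a raw (pre-normalization) sample-by-analyte table under the
#' configured study design, plus a ground-truth record listing which
#' analytes were planted as positive or negative correlates of the
#' hypoxia+bFGF target condition (effects in other conditions, e.g. the
#' hypoxia-alone correlates, count as null with respect to that target).
#' Total protein is drawn once per sample from the configuration seed, so
#' the cytokine and phospho panels generated from the same config share
#' their samples' total-protein values, as two assays on the same cultures
#' would.
#'
#' @param config a [syntheticConfig()] object.
#' @param panel `"cytokine"` or `"phospho"`.
#' @return `list(table = AnalyteExperiment, truth = list(planted_positive,
#'   planted_negative, null_analytes, config))`.
#' @examples
#' gp <- generatePanel(syntheticConfig(seed = 42), "cytokine")
#' gp$table
#' gp$truth$planted_positive
#' @export
generatePanel <- function(config, panel = c("cytokine", "phospho")) {
  stopifnot(inherits(config, "SyntheticConfig"))
  panel <- match.arg(panel)
  conds <- rep(config$conditions, config$nPerCondition)
  n <- length(conds)
  if (n < 2) stop("design must have at least 2 samples")
  analytes <- .panelAnalytes(config, panel)
  p <- length(analytes)
  pEff <- config$effects[[panel]]
  sdl <- config$noiseSd
  # condition multiplier realizing an effect of e within-condition SDs
  multiplier <- function(analyte, condition) {
    e <- pEff[[analyte]][condition]
    if (is.null(e) || is.na(e)) return(1)
    if (config$noiseModel == "lognormal") exp(e * sdl) else 1 + e * sdl
  }
  tpRef <- mean(config$totalProteinMeans[config$conditions])

  out <- withSeed(config$seed, function() {
    tpMean <- config$totalProteinMeans[conds]
    tp <- stats::rlnorm(n, meanlog = log(tpMean) - 0.1^2 / 2, sdlog = 0.1)
    vals <- matrix(0, n, p, dimnames = list(NULL, analytes))
    for (j in seq_len(p)) {
      mult <- vapply(conds, function(cc) multiplier(analytes[j], cc),
                     numeric(1))
      base <- config$baselineMean * mult * tp / tpRef
      if (config$noiseModel == "lognormal") {
        vals[, j] <- base * stats::rlnorm(n, meanlog = -sdl^2 / 2,
                                          sdlog = sdl)
      } else {
        vals[, j] <- pmax(base + stats::rnorm(n, 0,
                                              config$baselineMean * sdl), 0)
      }
    }
    list(tp = tp, vals = vals)
  })

  sampleIds <- paste0(conds, "_", unlist(lapply(config$nPerCondition,
                                                seq_len)))
  tab <- AnalyteExperiment(out$vals, sampleIds = sampleIds,
                           conditions = conds, totalProtein = out$tp,
                           panel = panel, analyteNames = analytes)
  target <- "hypoxia_bFGF"
  eff <- vapply(analytes, function(a) {
    e <- pEff[[a]][target]
    if (is.null(e) || is.na(e)) 0 else unname(e)
  }, numeric(1))
  truth <- list(planted_positive = analytes[eff > 0],
                planted_negative = analytes[eff < 0],
                null_analytes = analytes[eff == 0],
                target_condition = target,
                config = unclass(config)[setdiff(names(config), "effects")])
  list(table = tab, truth = truth)
}

#' Build the packaged default fixture
#'
#' Generates the deterministic two-panel fixture mirroring the emulated
#' study design — a 15 x 32 cytokine table and a 15 x 8 phospho table from
#' the same 15 cultures, with 3 planted positive and 2 planted negative
#' analytes per panel at 2-3 SD — and optionally writes them (plus the
#' ground truth as JSON) as delimited text that [readAnalyteTable()]
#' consumes.
#'
#' @param seed integer seed (default 101, the packaged fixture's seed).
#' @param dir optional output directory (created if needed); when `NULL`
#'   nothing is written.
#' @return `list(cytokine =, phospho =, truth = list(cytokine =, phospho =))`.
#' @export
makeDefaultFixture <- function(seed = 101L, dir = NULL) {
  config <- syntheticConfig(seed = seed)
  cyt <- generatePanel(config, "cytokine")
  pho <- generatePanel(config, "phospho")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    writeAnalyteTable(cyt$table, file.path(dir, "cytokine_panel_synthetic.csv"))
    writeAnalyteTable(pho$table, file.path(dir, "phospho_panel_synthetic.csv"))
    jsonlite::write_json(list(cytokine = cyt$truth[1:4],
                              phospho = pho$truth[1:4], seed = seed),
                         file.path(dir, "ground_truth_synthetic.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(cytokine = cyt$table, phospho = pho$table,
       truth = list(cytokine = cyt$truth, phospho = pho$truth))
}

#' Write an analyte table as delimited text
#'
#' Emits the same layout [readAnalyteTable()] consumes: `sample_id`,
#' `condition`, `total_protein`, then one column per analyte.
#'
#' @param x an [AnalyteExperiment-class].
#' @param path output file; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
writeAnalyteTable <- function(x, path) {
  stopifnot(methods::is(x, "AnalyteExperiment"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = sampleIds(x),
                   condition = sampleConditions(x),
                   total_protein = totalProtein(x),
                   measurementMatrix(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
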