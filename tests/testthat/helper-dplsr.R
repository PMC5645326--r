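# Shared fixtures built in code.

# Small hand-written analyte table: 4 samples x 3 analytes, 2 conditions.
tinyTable <- function(tp = c(10, 20, 10, 20)) {
  v <- matrix(c(1, 2, 3, 4,
                10, 20, 30, 40,
                5, 6, 7, 9), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("a1", "a2", "a3")))
  AnalyteExperiment(v, sampleIds = rownames(v),
                    conditions = c("A", "A", "B", "B"),
                    totalProtein = tp, panel = "cytokine")
}

# Write an AnalyteExperiment-shaped data.frame to a temp csv and return the
# path (for ingest error-path tests that need malformed files).
writeTmpCsv <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
  f
}

# Full-data model fit for one synthetic panel: z-scored matrix, design,
# rotated model.
fitPanel <- function(seed = 101, panel = "cytokine",
                     target = "hypoxia_bFGF", config = NULL,
                     normalize = TRUE) {
  if (is.null(config)) config <- syntheticConfig(seed = seed)
  tab <- generatePanel(config, panel)$table
  if (normalize) tab <- normalizeTotalProtein(tab)
  nm <- zscoreColumns(tab)
  design <- encodeDiscriminant(sampleConditions(nm), target)
  model <- rotateForSeparation(fitPLS(nm, design), design)
  list(nm = nm, design = design, model = model)
}

# A zero-effect (pure noise) configuration.
nullConfig <- function(seed) {
  syntheticConfig(seed = seed,
                  effects = list(cytokine = list(), phospho = list()))
}

# Valid hand-built PLSModel from prescribed orthogonal score columns
# (for rotation tests that need exact score geometry).
toyModel <- function(t1, t2) {
  stopifnot(abs(sum(t1 * t2)) < 1e-12)
  Tm <- cbind(t1, t2)
  p <- 3
  W <- cbind(c(1, 0, 0), c(0, 1, 0))
  P <- W
  methods::new("PLSModel", nComponents = 2L, xWeights = W, xLoadings = P,
               xScores = Tm, yLoadings = matrix(0, 2, 2),
               converged = c(TRUE, TRUE), iterationsUsed = c(1L, 1L),
               explainedXVariance = c(0.5, 0.5),
               analyteNames = paste0("a", 1:p))
}
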