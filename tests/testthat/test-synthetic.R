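test_that("the generator is seed-deterministic and matches the study design", {
  cfg <- syntheticConfig(seed = 81)
  a <- generatePanel(cfg, "cytokine")
  b <- generatePanel(cfg, "cytokine")
  expect_identical(measurementMatrix(a$table), measurementMatrix(b$table))
  expect_identical(totalProtein(a$table), totalProtein(b$table))
  expect_equal(dim(measurementMatrix(a$table)), c(15, 32))  # 3+4+4+4
  ph <- generatePanel(cfg, "phospho")
  expect_equal(dim(measurementMatrix(ph$table)), c(15, 8))
  expect_equal(as.vector(table(sampleConditions(a$table))[
    c("normoxia", "normoxia_bFGF", "hypoxia", "hypoxia_bFGF")]),
    c(3, 4, 4, 4))
  # the two panels are assays of the same cultures: same total protein
  expect_identical(totalProtein(a$table), totalProtein(ph$table))
  # ground truth partitions the analyte set
  tr <- a$truth
  expect_setequal(c(tr$planted_positive, tr$planted_negative,
                    tr$null_analytes), analyteNames(a$table))
  expect_length(intersect(tr$planted_positive, tr$planted_negative), 0)
  expect_length(tr$planted_positive, 3)
  expect_length(tr$planted_negative, 2)
})

test_that("all generated measurements stay positive-valued", {
  for (seed in c(1, 2, 3, 4, 5)) {
    for (model in c("lognormal", "gaussian")) {
      g <- generatePanel(syntheticConfig(seed = seed, noiseModel = model),
                         "cytokine")
      expect_true(all(measurementMatrix(g$table) >= 0))
      expect_true(all(totalProtein(g$table) > 0))
    }
  }
})

test_that("with no planted effects, group means differ only by chance", {
  # target-vs-rest standardized mean gaps should rarely exceed 3 SE
  frac <- vapply(1:100, function(seed) {
    g <- generatePanel(nullConfig(seed), "cytokine")
    m <- measurementMatrix(normalizeTotalProtein(g$table))
    isT <- sampleConditions(g$table) == "hypoxia_bFGF"
    z <- apply(m, 2, function(x) {
      se <- sqrt(var(x[isT]) / sum(isT) + var(x[!isT]) / sum(!isT))
      abs(mean(x[isT]) - mean(x[!isT])) / se
    })
    mean(z < 3)
  }, numeric(1))
  expect_gte(mean(frac), 0.95)
})

test_that("planted effect sizes are realized on the normalized scale", {
  planted <- vapply(defaultEffects("cytokine"),
                    function(e) unname(e["hypoxia_bFGF"])[1], numeric(1))
  planted <- planted[!is.na(planted)]
  emp <- matrix(NA_real_, 100, length(planted),
                dimnames = list(NULL, names(planted)))
  for (seed in 1:100) {
    g <- generatePanel(syntheticConfig(seed = seed), "cytokine")
    m <- measurementMatrix(normalizeTotalProtein(g$table))
    isT <- sampleConditions(g$table) == "hypoxia_bFGF"
    for (an in colnames(emp)) {
      x <- m[, an]
      sp <- sqrt((var(x[isT]) + var(x[!isT])) / 2)
      emp[seed, an] <- (mean(x[isT]) - mean(x[!isT])) / sp
    }
  }
  avg <- colMeans(emp)
  expect_true(all(abs(avg - planted) <= 0.5 * abs(planted)))
})

test_that("total-protein structure creates a confound normalization removes", {
  # zero planted effects + condition-dependent protein: raw values carry
  # spurious condition separation that dividing by protein removes
  gaps <- vapply(1:20, function(seed) {
    cfg <- nullConfig(seed)
    raw <- fitPanel(config = cfg, normalize = FALSE)
    nrm <- fitPanel(config = cfg, normalize = TRUE)
    separationScore(raw$model) - separationScore(nrm$model)
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("the packaged fixture regenerates and round-trips identically", {
  dir <- tempfile()
  fx <- makeDefaultFixture(seed = 101, dir = dir)
  expect_true(all(file.exists(file.path(dir,
    c("cytokine_panel_synthetic.csv", "phospho_panel_synthetic.csv",
      "ground_truth_synthetic.json")))))
  back <- readAnalyteTable(file.path(dir, "cytokine_panel_synthetic.csv"),
                           "cytokine")
  expect_equal(measurementMatrix(back), measurementMatrix(fx$cytokine),
               tolerance = 1e-12)
  # the copy shipped with the package is the same fixture
  shipped <- system.file("extdata", "cytokine_panel_synthetic.csv",
                         package = "dplsr")
  expect_true(nzchar(shipped))
  expect_equal(measurementMatrix(readAnalyteTable(shipped, "cytokine")),
               measurementMatrix(fx$cytokine), tolerance = 1e-12)
})

test_that("invalid generator configurations are rejected", {
  expect_error(syntheticConfig(nPerCondition = c(3, 4, 4)), "per condition")
  expect_error(syntheticConfig(nPerCondition = c(0, 4, 4, 4)), "at least one")
  expect_error(syntheticConfig(noiseSd = 0), "noiseSd")
  expect_error(syntheticConfig(nCytokines = 0), "panel sizes")
  expect_error(syntheticConfig(totalProteinMeans = c(normoxia = 8)),
               "every condition")
  expect_error(
    syntheticConfig(effects = list(cytokine = list(x = c(nowhere = 2)),
                                   phospho = list())),
    "unknown condition")
})
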