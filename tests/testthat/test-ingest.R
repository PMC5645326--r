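test_that("a study-sized table round-trips through the reader intact", {
  fx <- makeDefaultFixture(seed = 101)
  f <- tempfile(fileext = ".csv")
  writeAnalyteTable(fx$cytokine, f)
  tab <- readAnalyteTable(f, panel = "cytokine")
  expect_s4_class(tab, "AnalyteExperiment")
  expect_equal(dim(measurementMatrix(tab)), c(15, 32))
  expect_identical(sampleIds(tab), sampleIds(fx$cytokine))       # row order
  expect_identical(analyteNames(tab), analyteNames(fx$cytokine)) # col order
  expect_identical(sampleConditions(tab), sampleConditions(fx$cytokine))
  expect_equal(length(unique(sampleConditions(tab))), 4)
})

test_that("malformed input files are rejected with informative errors", {
  df <- data.frame(sample_id = c("s1", "s2", "s3"),
                   condition = c("A", "A", "B"),
                   total_protein = c(5, 5, 5),
                   a1 = c(1, 2, 3), a2 = c(4, 5, 6))
  # missing required column, named in the message
  expect_error(readAnalyteTable(
    writeTmpCsv(df[setdiff(names(df), "total_protein")]), "cytokine"),
    "total_protein")
  # non-positive total protein names the sample
  bad <- df; bad$total_protein[2] <- 0
  expect_error(readAnalyteTable(writeTmpCsv(bad), "cytokine"), "s2")
  # negative measurement names sample and analyte
  bad <- df; bad$a2[3] <- -1
  err <- expect_error(readAnalyteTable(writeTmpCsv(bad), "cytokine"))
  expect_match(conditionMessage(err), "s3")
  expect_match(conditionMessage(err), "a2")
  # duplicate sample ids
  bad <- df; bad$sample_id[2] <- "s1"
  expect_error(readAnalyteTable(writeTmpCsv(bad), "cytokine"), "duplicate")
  # missing entries are rejected, not imputed
  bad <- df; bad$a1[1] <- NA
  expect_error(readAnalyteTable(writeTmpCsv(bad), "cytokine"), "missing")
  expect_error(readAnalyteTable(tempfile(), "cytokine"), "not found")
})

test_that("total-protein normalization divides rows by their own protein", {
  tab <- tinyTable(tp = c(50, 10, 20, 10))
  norm <- normalizeTotalProtein(tab)
  expect_equal(measurementMatrix(norm)["s1", "a2"], 10 / 50)
  expect_equal(unname(measurementMatrix(norm)[, "a1"]),
               c(1, 2, 3, 4) / c(50, 10, 20, 10))
  # total protein retained for audit; stage advanced
  expect_equal(totalProtein(norm), c(50, 10, 20, 10))
  expect_identical(S4Vectors::metadata(norm)$stage, "protein_normalized")
  # identical raw rows with protein 10 vs 20 end up a factor 2 apart
  v <- matrix(rep(c(4, 8, 2), each = 2), 2,
              dimnames = list(c("x", "y"), c("a1", "a2", "a3")))
  two <- AnalyteExperiment(v, c("x", "y"), c("A", "B"),
                           totalProtein = c(10, 20), panel = "phospho")
  nm <- measurementMatrix(normalizeTotalProtein(two))
  expect_equal(unname(nm["x", ] / nm["y", ]), rep(2, 3))
})

test_that("uniform total protein leaves per-analyte sample rankings unchanged", {
  tab <- tinyTable(tp = rep(7, 4))
  m0 <- measurementMatrix(tab)
  m1 <- measurementMatrix(normalizeTotalProtein(tab))
  for (j in seq_len(ncol(m0)))
    expect_identical(order(m0[, j]), order(m1[, j]))
})

test_that("z-scoring gives exact mean-0, sd-1 columns and keeps row order", {
  tab <- tinyTable()
  nm <- zscoreColumns(tab)
  z <- as.matrix(nm)
  expect_equal(unname(z[, "a1"]), c(-3, -1, 1, 3) / sqrt(5 / 3) / 2,
               tolerance = 1e-12)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-10))
  # column statistics recorded for audit (n-1 denominator)
  expect_equal(nm@columnMeans, unname(colMeans(measurementMatrix(tab))))
  expect_equal(nm@columnSds,
               unname(apply(measurementMatrix(tab), 2, sd)))
  # sample order and condition labels never permuted
  expect_identical(rownames(z), sampleIds(tab))
  expect_identical(sampleConditions(nm), sampleConditions(tab))
  # the documented 3-point example
  v <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  ae <- AnalyteExperiment(v, paste0("s", 1:3), c("A", "A", "B"),
                          totalProtein = rep(1, 3), panel = "cytokine")
  expect_equal(unname(as.matrix(zscoreColumns(ae))[, 1]), c(-1, 0, 1))
})

test_that("zero-variance analytes error by default and drop on request", {
  v <- matrix(c(1, 2, 3, 5, 5, 5), 3,
              dimnames = list(paste0("s", 1:3), c("ok", "flat")))
  ae <- AnalyteExperiment(v, rownames(v), c("A", "A", "B"),
                          totalProtein = rep(1, 3), panel = "cytokine")
  expect_error(zscoreColumns(ae), "flat")
  expect_warning(nm <- zscoreColumns(ae, onZeroVariance = "drop"), "flat")
  expect_identical(analyteNames(nm), "ok")
})

test_that("z-scoring is invariant to per-column positive affine transforms", {
  set.seed(11)
  for (rep in 1:5) {
    m <- matrix(abs(rnorm(60, 10, 2)), 10, 6,
                dimnames = list(paste0("s", 1:10), paste0("a", 1:6)))
    a <- runif(6, 0.5, 4)
    b <- runif(6, 1, 50)
    ae1 <- AnalyteExperiment(m, rownames(m), rep(c("A", "B"), 5),
                             totalProtein = rep(1, 10), panel = "cytokine")
    ae2 <- AnalyteExperiment(sweep(sweep(m, 2, a, "*"), 2, b, "+"),
                             rownames(m), rep(c("A", "B"), 5),
                             totalProtein = rep(1, 10), panel = "cytokine")
    expect_equal(as.matrix(zscoreColumns(ae1)),
                 as.matrix(zscoreColumns(ae2)), tolerance = 1e-10)
  }
  # idempotence: re-standardizing already-standard columns reproduces them
  # (shifting the z-scores into positive territory is itself affine)
  z <- as.matrix(zscoreColumns(tinyTable()))
  ae3 <- AnalyteExperiment(z + 10, rownames(z), rep(c("A", "B"), 2),
                           totalProtein = rep(1, 4), panel = "cytokine")
  expect_equal(as.matrix(zscoreColumns(ae3)), z, tolerance = 1e-10)
})

test_that("the normalized matrix writes with its z-scoring sidecar", {
  nm <- zscoreColumns(normalizeTotalProtein(tinyTable()))
  f <- tempfile(fileext = ".csv")
  writeNormalizedMatrix(nm, f)
  expect_true(file.exists(f))
  side <- jsonlite::read_json(paste0(f, ".json"), simplifyVector = TRUE)
  expect_equal(side$column_sds, nm@columnSds, tolerance = 1e-12)
  expect_identical(side$sd_denominator, "n-1")
  back <- utils::read.csv(f, check.names = FALSE)
  expect_equal(as.matrix(back[, analyteNames(nm)]), as.matrix(nm),
               ignore_attr = TRUE, tolerance = 1e-6)
})
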