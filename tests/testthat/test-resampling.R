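test_that("the subsample size follows half-up rounding with a floor of 2", {
  expect_identical(subsampleSize(15, 0.8), 12L)
  expect_identical(subsampleSize(10, 1.0), 10L)
  expect_identical(subsampleSize(10, 0.85), 9L)  # 8.5 rounds up
  expect_identical(subsampleSize(10, 0.05), 2L)  # clamped to 2
  expect_identical(subsampleSize(4, 0.5), 2L)
  expect_error(subsampleSize(1, 0.8), ">= 2")
  expect_error(subsampleSize(10, 0), "fraction")
  expect_error(subsampleSize(10, 1.2), "fraction")
})

test_that("sign correction aligns a subsampled LV with the total model's", {
  lv <- c(0.2, -0.5, 0.8)
  expect_equal(signCorrect(-lv, lv), lv)     # flip corrected
  expect_equal(signCorrect(lv, lv), lv)      # identity
  orth <- c(0.5, 0.2, 0)                     # dot = 0 -> +1 convention
  expect_equal(signCorrect(orth, c(0, 0, 1)), orth)
  expect_error(signCorrect(c(1, 2), c(1, 2, 3)), "length")
  expect_error(signCorrect(lv, c(0, 0, 0)), "all-zero")
})

test_that("Monte Carlo subsampling is seeded, reproducible, and sign-consistent", {
  fit <- fitPanel(seed = 61, panel = "phospho")
  cfg <- monteCarloConfig(nIterations = 150, seed = 9)
  s1 <- monteCarloLoadings(fit$nm, fit$model, fit$design, cfg)
  s2 <- monteCarloLoadings(fit$nm, fit$model, fit$design, cfg)
  expect_identical(s1@lv1Mean, s2@lv1Mean)   # bit-identical rerun
  expect_identical(s1@lv2Sd, s2@lv2Sd)
  expect_identical(s1@redrawCount, s2@redrawCount)
  expect_identical(s1@subsampleN, 12L)       # 0.8 of 15
  expect_true(all(s1@signDots >= 0))         # post-correction alignment
  expect_true(all(c(s1@lv1Sd, s1@lv2Sd) >= 0))
  expect_length(s1@lv1Mean, 8)
  # a different seed gives different draws
  s3 <- monteCarloLoadings(fit$nm, fit$model, fit$design,
                           monteCarloConfig(nIterations = 150, seed = 10))
  expect_false(identical(s1@lv1Mean, s3@lv1Mean))
  # calling does not disturb the caller's RNG stream
  set.seed(77); before <- rnorm(3)
  set.seed(77)
  invisible(monteCarloLoadings(fit$nm, fit$model, fit$design, cfg))
  expect_identical(rnorm(3), before)
})

test_that("subsampling the full data gives exactly zero spread", {
  fit <- fitPanel(seed = 62, panel = "phospho")
  cfg <- monteCarloConfig(nIterations = 50, subsampleFraction = 1.0,
                          seed = 3)
  s <- monteCarloLoadings(fit$nm, fit$model, fit$design, cfg)
  expect_lt(max(s@lv1Sd), 1e-12)
  expect_lt(max(s@lv2Sd), 1e-12)
  # and the iteration means equal the total model's rotated loadings
  expect_equal(s@lv1Mean, unname(rotatedLoadings(fit$model)[, 1]),
               tolerance = 1e-10)
})

test_that("stored iterations carry the rotated per-iteration loadings", {
  fit <- fitPanel(seed = 63, panel = "phospho")
  cfg <- monteCarloConfig(nIterations = 20, seed = 4)
  s <- monteCarloLoadings(fit$nm, fit$model, fit$design, cfg,
                          storeIterations = TRUE)
  expect_length(s@iterationLoadings, 20)
  expect_equal(dim(s@iterationLoadings[[1]]), c(8, 2))
  stacked <- vapply(s@iterationLoadings, function(m) m[, 1],
                    numeric(8))
  expect_equal(unname(rowMeans(stacked)), s@lv1Mean, tolerance = 1e-12)
  expect_equal(unname(apply(stacked, 1, sd)), s@lv1Sd, tolerance = 1e-12)
})

test_that("draws that empty a condition are redrawn, within a budget", {
  # 1 sample in condition A out of 11; keeping 4 of 11 usually drops A
  set.seed(71)
  conds <- c("A", rep("B", 5), rep("C", 5))
  X <- matrix(rnorm(11 * 4), 11, 4,
              dimnames = list(paste0("s", 1:11), paste0("a", 1:4)))
  X <- scale(X, scale = apply(X, 2, sd))
  nm <- methods::new("NormalizedMatrix", matrix = X[, ], conditions = conds,
                     columnMeans = rep(0, 4), columnSds = rep(1, 4),
                     panel = "cytokine")
  d <- encodeDiscriminant(conds, "C")
  rot <- rotateForSeparation(fitPLS(as.matrix(nm), d), d)
  ok <- monteCarloLoadings(nm, rot, d,
                           monteCarloConfig(nIterations = 30,
                                            subsampleFraction = 0.36,
                                            seed = 8))
  expect_gt(ok@redrawCount, 0)   # the guard actually engaged
  expect_error(
    monteCarloLoadings(nm, rot, d,
                       monteCarloConfig(nIterations = 200,
                                        subsampleFraction = 0.36, seed = 8,
                                        maxRedrawsPerIteration = 0L)),
    "redraws")
})

test_that("loading spread shrinks as the subsample fraction grows", {
  diffs <- vapply(1:20, function(seed) {
    fit <- fitPanel(seed = 200 + seed, panel = "phospho")
    hi <- monteCarloLoadings(fit$nm, fit$model, fit$design,
                             monteCarloConfig(100, 0.93, seed = seed))
    lo <- monteCarloLoadings(fit$nm, fit$model, fit$design,
                             monteCarloConfig(100, 0.60, seed = seed))
    mean(lo@lv1Sd) - mean(hi@lv1Sd)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("analytes rank by mean LV1 loading with alphabetical ties", {
  s <- methods::new("MonteCarloSummary",
                    analyteNames = c("a", "b", "c"),
                    lv1Mean = c(0.5, -0.9, 0.1), lv1Sd = rep(0, 3),
                    lv2Mean = rep(0, 3), lv2Sd = rep(0, 3),
                    nIterationsUsed = 1L, redrawCount = 0L,
                    subsampleN = 2L, config = monteCarloConfig(1, 1, 1),
                    signDots = matrix(0, 1, 2), iterationLoadings = list())
  expect_identical(rankCorrelates(s), c("a", "c", "b"))
  s@lv1Mean <- rep(0.2, 3)
  expect_identical(rankCorrelates(s), c("a", "b", "c"))  # tie-break
  s@lv1Mean <- c(0.5, -0.9, 0.1)
  sNeg <- s; sNeg@lv1Mean <- -s@lv1Mean
  expect_identical(rankCorrelates(sNeg), rev(rankCorrelates(s)))
  tab <- mcTable(s)
  expect_identical(tab$rank, c(1L, 3L, 2L))
})
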