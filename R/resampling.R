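#' @include rotation.R
NULL

#' Number of samples per subsampling iteration
#'
#' `round(fraction * nSamples)` with half-up rounding (so 80 percent of 15
#' is 12, and 0.85 of 10 rounds 8.5 up to 9), clamped to `[2, nSamples]`
#' so every refit stays well-posed.
#'
#' @param nSamples total number of samples (>= 2).
#' @param fraction subsample fraction in (0, 1].
#' @return An integer subsample size.
#' @examples
#' subsampleSize(15, 0.8)  # 12
#' @export
subsampleSize <- function(nSamples, fraction) {
  nSamples <- as.integer(nSamples)
  if (nSamples < 2) stop("nSamples must be >= 2")
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0, 1]")
  m <- floor(fraction * nSamples + 0.5)  # half-up, not banker's rounding
  as.integer(min(max(m, 2), nSamples))
}

#' Correct the sign indeterminacy of a subsampled latent variable
#'
#' Latent vectors are defined only up to sign; a refit on a subsample can
#' return the mirrored solution. The correction multiplies the subsample LV
#' by the sign of its scalar product with the corresponding LV of the
#' total model; a zero scalar product leaves the vector unchanged
#' (`sign(0)` is taken as `+1`).
#'
#' @param lvSub numeric vector, an LV (loading vector) from a subsample
#'   refit.
#' @param lvTotal the corresponding LV from the total model; same length,
#'   not all zero.
#' @return `lvSub * sign(lvSub . lvTotal)`.
#' @export
signCorrect <- function(lvSub, lvTotal) {
  if (length(lvSub) != length(lvTotal))
    stop("length mismatch between subsample LV and total-model LV")
  if (all(lvTotal == 0))
    stop("total-model LV is all-zero")
  s <- sum(lvSub * lvTotal)
  if (s < 0) -lvSub else lvSub
}

#' Monte Carlo subsampling of rotated loadings
#'
#' Characterizes the uncertainty of the rotated LV1/LV2 loadings by
#' refitting the discriminant PLS model on random subsamples. Each
#' iteration draws `subsampleSize(n, fraction)` samples without
#' replacement (uniformly, unstratified); a draw that leaves any condition
#' with no samples is redrawn (each redraw counts against the per-iteration
#' budget). The subsample inherits the full-data z-scoring — columns are
#' not re-standardized per iteration (set `rezscore = TRUE` to opt in).
#' The refit uses the same number of components and the same condition
#' order as the total model; its LV1/LV2 loadings are sign-corrected
#' against the total model's *unrotated* loadings ([signCorrect()]), then
#' the total model's rotation angle is applied, and per-analyte means and
#' SDs (n-1 denominator) are accumulated across iterations.
#'
#' All random draws come from one generator seeded with `config@seed` and
#' are consumed strictly in iteration order (redraws included), so a run
#' is reproducible from the seed alone.
#'
#' @param data a [NormalizedMatrix-class] — the matrix the total model was
#'   fitted on.
#' @param totalModel the [RotatedModel-class] fitted on the full data.
#' @param design the full-data [DiscriminantDesign-class].
#' @param config a [MonteCarloConfig-class] (see [monteCarloConfig()]).
#' @param storeIterations keep every iteration's rotated loadings (for
#'   diagnostics); off by default.
#' @param rezscore re-z-score each subsample before refitting (off by
#'   default; the standard procedure standardizes once, before modeling).
#' @return A [MonteCarloSummary-class].
#' @seealso [rankCorrelates()], [mcTable()]
#' @export
monteCarloLoadings <- function(data, totalModel, design, config,
                               storeIterations = FALSE, rezscore = FALSE) {
  stopifnot(methods::is(data, "NormalizedMatrix"),
            methods::is(totalModel, "RotatedModel"),
            methods::is(design, "DiscriminantDesign"),
            methods::is(config, "MonteCarloConfig"))
  X <- data@matrix
  n <- nrow(X)
  p <- ncol(X)
  if (nrow(totalModel@base@xScores) != n)
    stop("total model was not fitted on this data (sample count differs)")
  m <- subsampleSize(n, config@subsampleFraction)
  conds <- data@conditions
  condOrder <- design@conditionOrder
  target <- design@targetCondition
  A <- totalModel@base@nComponents
  Ptot <- totalModel@base@xLoadings[, 1:2, drop = FALSE]
  R <- rotationMatrix(totalModel@theta)
  nIter <- config@nIterations

  lv1 <- matrix(NA_real_, nIter, p)
  lv2 <- matrix(NA_real_, nIter, p)
  dots <- matrix(NA_real_, nIter, 2,
                 dimnames = list(NULL, c("LV1", "LV2")))
  kept <- if (storeIterations) vector("list", nIter) else list()
  redrawCount <- 0L

  withSeed(config@seed, function() {
    for (i in seq_len(nIter)) {
      redraws <- 0L
      repeat {
        idx <- sample.int(n, m)
        if (all(condOrder %in% conds[idx])) break
        redraws <- redraws + 1L
        if (redraws > config@maxRedrawsPerIteration) {
          tab <- table(factor(conds[idx], levels = condOrder))
          stop("iteration ", i, ": exceeded ", config@maxRedrawsPerIteration,
               " redraws; last draw had condition counts ",
               paste(sprintf("%s=%d", names(tab), as.integer(tab)),
                     collapse = ", "))
        }
      }
      redrawCount <<- redrawCount + redraws
      Xsub <- X[idx, , drop = FALSE]
      if (rezscore) {
        mu <- colMeans(Xsub)
        sdev <- apply(Xsub, 2, stats::sd)
        if (any(sdev == 0))
          stop("iteration ", i,
               ": zero-variance column under rezscore = TRUE")
        Xsub <- sweep(sweep(Xsub, 2, mu, "-"), 2, sdev, "/")
      }
      dsub <- encodeDiscriminant(conds[idx], target,
                                 conditionOrder = condOrder)
      fit <- fitPLS(Xsub, dsub, nComponents = A, checkCentered = FALSE)
      Psub <- fit@xLoadings[, 1:2, drop = FALSE]
      # joint flip: the whole LV (loading vector) is mirrored, keeping the
      # refit self-consistent
      s1 <- sum(Psub[, 1] * Ptot[, 1]); s1 <- if (s1 < 0) -1 else 1
      s2 <- sum(Psub[, 2] * Ptot[, 2]); s2 <- if (s2 < 0) -1 else 1
      Pc <- cbind(Psub[, 1] * s1, Psub[, 2] * s2)
      dots[i, ] <<- c(sum(Pc[, 1] * Ptot[, 1]), sum(Pc[, 2] * Ptot[, 2]))
      Pr <- Pc %*% R
      lv1[i, ] <<- Pr[, 1]
      lv2[i, ] <<- Pr[, 2]
      if (storeIterations) kept[[i]] <<- Pr
    }
  })

  sdIter <- function(M) {
    if (nrow(M) > 1) apply(M, 2, stats::sd) else rep(0, ncol(M))
  }
  methods::new("MonteCarloSummary",
    analyteNames = totalModel@base@analyteNames,
    lv1Mean = colMeans(lv1), lv1Sd = sdIter(lv1),
    lv2Mean = colMeans(lv2), lv2Sd = sdIter(lv2),
    nIterationsUsed = nIter, redrawCount = redrawCount,
    subsampleN = m,
    config = config, signDots = dots, iterationLoadings = kept)
}

#' Rank analytes by their mean rotated-LV1 loading
#'
#' Orders analytes most-positive first — the ordering of the loading bar
#' chart, where positive values are the correlates of the target condition
#' and negative values its inverse correlates. Ties break alphabetically.
#'
#' @param summary a [MonteCarloSummary-class].
#' @return Character vector of analyte names, strongest positive correlate
#'   first.
#' @export
rankCorrelates <- function(summary) {
  stopifnot(methods::is(summary, "MonteCarloSummary"))
  ord <- order(-summary@lv1Mean, summary@analyteNames)
  summary@analyteNames[ord]
}

#' Write a Monte Carlo loading summary as delimited text
#'
#' One row per analyte: `analyte`, `lv1_mean`, `lv1_sd`, `lv2_mean`,
#' `lv2_sd`, `rank`.
#'
#' @param summary a [MonteCarloSummary-class].
#' @param path output file; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
writeMCSummary <- function(summary, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(mcTable(summary), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
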