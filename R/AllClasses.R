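#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------- ##
##  AnalyteExperiment                                               ##
## ---------------------------------------------------------------- ##

#' Sample-by-analyte measurement container
#'
#' `AnalyteExperiment` extends
#' [SummarizedExperiment::SummarizedExperiment-class] to hold one multiplexed
#' panel: analytes are rows, samples are columns, the single assay
#' `"exprs"` holds the measurements (cytokine pg/mL, or phospho assay
#' intensity units; measurement-per-microgram after total-protein
#' normalization). Per-sample metadata live in `colData`: `condition`
#' (culture condition label) and `total_protein` (micrograms per lysate,
#' the proliferation proxy used for normalization). `metadata(x)$panel` is
#' `"cytokine"` or `"phospho"`; `metadata(x)$stage` records whether the
#' values are `"raw"` or `"protein_normalized"`.
#'
#' Validity requires: no missing entries, all measurements non-negative,
#' all total protein strictly positive, unique sample identifiers and
#' analyte names, at least 2 samples and at least 2 distinct conditions.
#'
#' @seealso [readAnalyteTable()], [normalizeTotalProtein()], [zscoreColumns()]
#' @export
setClass("AnalyteExperiment", contains = "SummarizedExperiment")

.validAnalyteExperiment <- function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "total_protein") %in% colnames(cd)))
    return("colData must contain 'condition' and 'total_protein'")
  if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'exprs' is required")
  v <- SummarizedExperiment::assay(object, "exprs")
  if (anyNA(v))
    msg <- c(msg, "missing measurement entries are not allowed")
  if (!anyNA(v) && any(v < 0))
    msg <- c(msg, "measurements must be non-negative")
  tp <- cd$total_protein
  if (anyNA(tp) || any(tp <= 0))
    msg <- c(msg, "total_protein must be positive for every sample")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample_id")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate analyte names")
  if (ncol(object) < 2)
    msg <- c(msg, "at least 2 samples are required")
  if (length(unique(as.character(cd$condition))) < 2)
    msg <- c(msg, "at least 2 distinct conditions are required")
  pn <- S4Vectors::metadata(object)$panel
  if (is.null(pn) || !pn %in% c("cytokine", "phospho"))
    msg <- c(msg, "metadata 'panel' must be 'cytokine' or 'phospho'")
  if (length(msg)) msg else TRUE
}
setValidity("AnalyteExperiment", .validAnalyteExperiment)

#' Construct an AnalyteExperiment
#'
#' @param values numeric matrix, samples in rows and analytes in columns
#'   (the orientation of the delimited input files; stored transposed).
#' @param sampleIds character vector of unique sample labels.
#' @param conditions character vector of condition labels, one per sample.
#' @param totalProtein positive numeric vector, micrograms per sample.
#' @param panel `"cytokine"` or `"phospho"`.
#' @param analyteNames optional; defaults to `colnames(values)`.
#' @param stage `"raw"` (default) or `"protein_normalized"`.
#' @return A validated [AnalyteExperiment-class] object.
#' @examples
#' v <- matrix(abs(rnorm(12, 10)), 4, 3,
#'             dimnames = list(paste0("s", 1:4), paste0("a", 1:3)))
#' AnalyteExperiment(v, rownames(v), c("A", "A", "B", "B"),
#'                   totalProtein = rep(5, 4), panel = "cytokine")
#' @export
AnalyteExperiment <- function(values, sampleIds, conditions, totalProtein,
                              panel = c("cytokine", "phospho"),
                              analyteNames = colnames(values),
                              stage = "raw") {
  panel <- match.arg(panel)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(analyteNames))
    analyteNames <- paste0("analyte_", seq_len(ncol(values)))
  dimnames(values) <- list(as.character(sampleIds), as.character(analyteNames))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = t(values)),
    colData = S4Vectors::DataFrame(
      condition = as.character(conditions),
      total_protein = as.numeric(totalProtein),
      row.names = as.character(sampleIds)),
    metadata = list(panel = panel, stage = stage))
  methods::new("AnalyteExperiment", se)
}

## ---------------------------------------------------------------- ##
##  NormalizedMatrix                                                ##
## ---------------------------------------------------------------- ##

#' Z-scored modeling matrix
#'
#' The product of [zscoreColumns()]: an `n x p` samples-by-analytes matrix
#' whose every column has mean 0 and sample standard deviation 1, together
#' with the column means and SDs removed by the z-scoring (so the
#' transformation is auditable and invertible), the per-sample condition
#' labels, and the panel identity.
#'
#' @slot matrix numeric `n x p` matrix (samples x analytes), z-scored.
#' @slot conditions character, length `n`.
#' @slot columnMeans,columnSds numeric, length `p`; the statistics of the
#'   (protein-normalized) input columns.
#' @slot panel `"cytokine"` or `"phospho"`.
#' @export
setClass("NormalizedMatrix",
  slots = c(matrix = "matrix", conditions = "character",
            columnMeans = "numeric", columnSds = "numeric",
            panel = "character"))

setValidity("NormalizedMatrix", function(object) {
  m <- object@matrix
  p <- ncol(m)
  if (length(object@conditions) != nrow(m))
    return("conditions length must equal the number of rows")
  if (length(object@columnMeans) != p || length(object@columnSds) != p)
    return("columnMeans/columnSds must have one entry per analyte")
  cm <- colMeans(m)
  csd <- apply(m, 2, stats::sd)
  if (any(abs(cm) >= 1e-10))
    return("every column must have |mean| < 1e-10")
  if (any(abs(csd - 1) >= 1e-10))
    return("every column must have |sd - 1| < 1e-10")
  TRUE
})

## ---------------------------------------------------------------- ##
##  DiscriminantDesign                                              ##
## ---------------------------------------------------------------- ##

#' One-hot discriminant response design
#'
#' Encodes the categorical condition labels as the response block of a
#' discriminant PLS regression: a one-hot `n x k` indicator matrix over the
#' `k` conditions (columns in first-appearance order unless an explicit
#' order is supplied) and its column-centered copy, plus the target
#' condition that the rotation stage will separate.
#'
#' @slot conditionOrder character, the `k` condition labels in column order.
#' @slot indicator `n x k` 0/1 matrix; each row sums to exactly 1.
#' @slot centered the indicator with column means subtracted.
#' @slot targetCondition one element of `conditionOrder`.
#' @seealso [encodeDiscriminant()]
#' @export
setClass("DiscriminantDesign",
  slots = c(conditionOrder = "character", indicator = "matrix",
            centered = "matrix", targetCondition = "character"))

setValidity("DiscriminantDesign", function(object) {
  ind <- object@indicator
  k <- length(object@conditionOrder)
  if (k < 2) return("at least 2 conditions are required")
  if (ncol(ind) != k) return("indicator must have one column per condition")
  if (!all(ind %in% c(0, 1)) || any(abs(rowSums(ind) - 1) > 0))
    return("each indicator row must be one-hot (sum exactly 1)")
  if (any(colSums(ind) < 1))
    return("every condition must have at least one sample")
  if (any(abs(colSums(object@centered)) >= 1e-10))
    return("centered columns must sum to 0")
  if (!object@targetCondition %in% object@conditionOrder)
    return("targetCondition must be one of conditionOrder")
  TRUE
})

## ---------------------------------------------------------------- ##
##  PLSModel / RotatedModel                                         ##
## ---------------------------------------------------------------- ##

#' Fitted PLS model
#'
#' Factor matrices of a two-block PLS fit by NIPALS (see [fitPLS()]):
#' X-weights `W` (`p x A`, unit-norm columns), X-loadings `P` (`p x A`),
#' X-scores `T` (`n x A`, mutually orthogonal columns), Y-loadings `Q`
#' (`k x A`), with per-component convergence diagnostics and the fraction
#' of X variance captured by each component. LV1 and LV2 are columns 1 and
#' 2 of the score/loading matrices.
#'
#' @slot nComponents integer, number of latent variables `A`.
#' @slot xWeights,xLoadings `p x A` matrices.
#' @slot xScores `n x A` matrix.
#' @slot yLoadings `k x A` matrix.
#' @slot converged,iterationsUsed per-component diagnostics.
#' @slot explainedXVariance numeric, length `A`, fractions of total X
#'   sum of squares.
#' @slot analyteNames character, length `p`.
#' @export
setClass("PLSModel",
  slots = c(nComponents = "integer",
            xWeights = "matrix", xLoadings = "matrix", xScores = "matrix",
            yLoadings = "matrix",
            converged = "logical", iterationsUsed = "integer",
            explainedXVariance = "numeric", analyteNames = "character"))

setValidity("PLSModel", function(object) {
  A <- object@nComponents
  Tm <- object@xScores
  W <- object@xWeights
  if (ncol(Tm) != A || ncol(W) != A || ncol(object@xLoadings) != A ||
      ncol(object@yLoadings) != A)
    return("all factor matrices must have nComponents columns")
  wn <- sqrt(colSums(W^2))
  if (any(abs(wn - 1) >= 1e-10))
    return("each x-weights column must have unit norm")
  if (A > 1) {
    G <- crossprod(Tm)
    nrm <- sqrt(diag(G))
    denom <- outer(nrm, nrm)
    off <- ifelse(denom > 0, abs(G) / denom, 0)  # zero columns pass trivially
    diag(off) <- 0
    if (any(off >= 1e-8))
      return("x-scores columns must be mutually orthogonal")
  }
  TRUE
})

#' PLS model with an in-plane orthogonal rotation
#'
#' A [PLSModel-class] whose LV1-LV2 plane has been rotated by angle
#' `theta` (radians, in `[0, 2*pi)`) so that the new LV1 best separates
#' the design's target condition; produced by [rotateForSeparation()].
#' Rotated scores and loadings are the base quantities right-multiplied by
#' the rotation matrix `[[cos, -sin], [sin, cos]]`; the sign convention
#' places the target condition's mean score on the positive (right) side
#' of rotated LV1.
#'
#' @slot base the underlying [PLSModel-class].
#' @slot theta rotation angle in radians.
#' @slot rotatedScores `n x 2`, rotated LV1/LV2 scores.
#' @slot rotatedLoadings `p x 2`, rotated LV1/LV2 loadings.
#' @slot separationScore the separation criterion value at `theta`.
#' @slot targetCondition the condition the rotation separates.
#' @export
setClass("RotatedModel",
  slots = c(base = "PLSModel", theta = "numeric",
            rotatedScores = "matrix", rotatedLoadings = "matrix",
            separationScore = "numeric", targetCondition = "character"))

setValidity("RotatedModel", function(object) {
  if (length(object@theta) != 1 || object@theta < 0 || object@theta >= 2 * pi)
    return("theta must be a single angle in [0, 2*pi)")
  if (ncol(object@rotatedScores) != 2 || ncol(object@rotatedLoadings) != 2)
    return("rotated scores/loadings must have exactly 2 columns")
  f1 <- sum(object@rotatedScores^2)
  f0 <- sum(object@base@xScores[, 1:2]^2)
  if (abs(f1 - f0) >= 1e-8 * max(1, f0))
    return("rotation must preserve the Frobenius norm of the score plane")
  TRUE
})

## ---------------------------------------------------------------- ##
##  MonteCarloConfig / MonteCarloSummary                            ##
## ---------------------------------------------------------------- ##

#' Monte Carlo subsampling configuration
#'
#' Parameters of the loading-uncertainty procedure: `nIterations` refits
#' (default 1000), each on a without-replacement subsample of
#' `round(subsampleFraction * n)` samples (default fraction 0.8, i.e. 12 of
#' 15 samples in the emulated study design), under a fixed `seed`. A draw
#' that leaves any condition without samples is redrawn, up to
#' `maxRedrawsPerIteration` times per iteration.
#'
#' @export
setClass("MonteCarloConfig",
  slots = c(nIterations = "integer", subsampleFraction = "numeric",
            seed = "integer", maxRedrawsPerIteration = "integer"))

setValidity("MonteCarloConfig", function(object) {
  if (object@nIterations < 1L) return("nIterations must be >= 1")
  f <- object@subsampleFraction
  if (!(f > 0 && f <= 1)) return("subsampleFraction must be in (0, 1]")
  if (object@maxRedrawsPerIteration < 0L)
    return("maxRedrawsPerIteration must be >= 0")
  TRUE
})

#' @param nIterations number of subsampling iterations (default 1000).
#' @param subsampleFraction fraction of samples kept per iteration
#'   (default 0.8).
#' @param seed integer seed driving all draws.
#' @param maxRedrawsPerIteration redraw budget per iteration when a draw
#'   empties a condition (default 100).
#' @return `monteCarloConfig()` returns a validated
#'   [MonteCarloConfig-class].
#' @rdname MonteCarloConfig-class
#' @export
monteCarloConfig <- function(nIterations = 1000L, subsampleFraction = 0.8,
                             seed = 1L, maxRedrawsPerIteration = 100L) {
  methods::new("MonteCarloConfig",
    nIterations = as.integer(nIterations),
    subsampleFraction = as.numeric(subsampleFraction),
    seed = as.integer(seed),
    maxRedrawsPerIteration = as.integer(maxRedrawsPerIteration))
}

#' Per-analyte Monte Carlo loading summary
#'
#' Mean and standard deviation (n-1 denominator), across subsampling
#' iterations, of each analyte's rotated, sign-corrected LV1 and LV2
#' loadings — the quantities drawn as bar heights and symmetric error bars.
#' `signDots` stores, per iteration, the scalar products of the corrected
#' subsample LVs with the total model's LVs (all must be non-negative);
#' `iterationLoadings` optionally stores every iteration's rotated loadings
#' when the summary was built with `storeIterations = TRUE`.
#'
#' @export
setClass("MonteCarloSummary",
  slots = c(analyteNames = "character",
            lv1Mean = "numeric", lv1Sd = "numeric",
            lv2Mean = "numeric", lv2Sd = "numeric",
            nIterationsUsed = "integer", redrawCount = "integer",
            subsampleN = "integer",
            config = "MonteCarloConfig",
            signDots = "matrix", iterationLoadings = "list"))

setValidity("MonteCarloSummary", function(object) {
  p <- length(object@analyteNames)
  lens <- c(length(object@lv1Mean), length(object@lv1Sd),
            length(object@lv2Mean), length(object@lv2Sd))
  if (any(lens != p))
    return("every per-analyte field must have length p")
  if (any(c(object@lv1Sd, object@lv2Sd) < 0))
    return("standard deviations must be non-negative")
  TRUE
})

## ---------------------------------------------------------------- ##
##  show methods                                                    ##
## ---------------------------------------------------------------- ##

setMethod("show", "AnalyteExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat(sprintf("AnalyteExperiment: %d samples x %d analytes [%s panel, %s]\n",
              ncol(object), nrow(object),
              S4Vectors::metadata(object)$panel,
              S4Vectors::metadata(object)$stage))
  tab <- table(cd$condition)
  cat("conditions:",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n")
})

setMethod("show", "NormalizedMatrix", function(object) {
  cat(sprintf("NormalizedMatrix: %d samples x %d analytes [%s panel], z-scored\n",
              nrow(object@matrix), ncol(object@matrix), object@panel))
})

setMethod("show", "DiscriminantDesign", function(object) {
  cat(sprintf("DiscriminantDesign: %d samples, %d conditions (target: %s)\n",
              nrow(object@indicator), length(object@conditionOrder),
              object@targetCondition))
  cat("condition order:", paste(object@conditionOrder, collapse = ", "), "\n")
})

setMethod("show", "PLSModel", function(object) {
  cat(sprintf("PLSModel: %d latent variables, %d samples x %d analytes\n",
              object@nComponents, nrow(object@xScores),
              nrow(object@xLoadings)))
  cat(sprintf("explained X variance: %s\n",
              paste(sprintf("LV%d %.1f%%", seq_len(object@nComponents),
                            100 * object@explainedXVariance),
                    collapse = ", ")))
  if (!all(object@converged))
    cat("warning: components", paste(which(!object@converged), collapse = ","),
        "did not converge\n")
})

setMethod("show", "RotatedModel", function(object) {
  cat(sprintf(
    "RotatedModel: theta = %.3f rad (%.1f deg), separation score %.3f (target: %s)\n",
    object@theta, object@theta * 180 / pi, object@separationScore,
    object@targetCondition))
  cat("base model:\n")
  methods::show(object@base)
})

setMethod("show", "MonteCarloConfig", function(object) {
  cat(sprintf(
    "MonteCarloConfig: %d iterations, fraction %.2f, seed %d, max redraws %d\n",
    object@nIterations, object@subsampleFraction, object@seed,
    object@maxRedrawsPerIteration))
})

setMethod("show", "MonteCarloSummary", function(object) {
  cat(sprintf(
    "MonteCarloSummary: %d analytes, %d iterations (%d redraws)\n",
    length(object@analyteNames), object@nIterationsUsed,
    object@redrawCount))
  top <- order(-object@lv1Mean)[seq_len(min(3, length(object@analyteNames)))]
  cat("top LV1 correlates:",
      paste(sprintf("%s (%.3f)", object@analyteNames[top],
                    object@lv1Mean[top]), collapse = ", "), "\n")
})

## ---------------------------------------------------------------- ##
##  accessors                                                       ##
## ---------------------------------------------------------------- ##

#' @rdname dplsr-generics
#' @export
setMethod("analyteNames", "AnalyteExperiment", function(x, ...) rownames(x))
#' @rdname dplsr-generics
#' @export
setMethod("sampleIds", "AnalyteExperiment", function(x, ...) colnames(x))
#' @rdname dplsr-generics
#' @export
setMethod("sampleConditions", "AnalyteExperiment", function(x, ...)
  as.character(SummarizedExperiment::colData(x)$condition))
#' @rdname dplsr-generics
#' @export
setMethod("totalProtein", "AnalyteExperiment", function(x, ...)
  as.numeric(SummarizedExperiment::colData(x)$total_protein))
#' @rdname dplsr-generics
#' @export
setMethod("panelType", "AnalyteExperiment", function(x, ...)
  S4Vectors::metadata(x)$panel)
#' @rdname dplsr-generics
#' @export
setMethod("measurementMatrix", "AnalyteExperiment", function(x, ...)
  t(SummarizedExperiment::assay(x, "exprs")))

#' @rdname dplsr-generics
#' @export
setMethod("analyteNames", "NormalizedMatrix", function(x, ...)
  colnames(x@matrix))
#' @rdname dplsr-generics
#' @export
setMethod("sampleIds", "NormalizedMatrix", function(x, ...)
  rownames(x@matrix))
#' @rdname dplsr-generics
#' @export
setMethod("sampleConditions", "NormalizedMatrix", function(x, ...)
  x@conditions)
#' @rdname dplsr-generics
#' @export
setMethod("panelType", "NormalizedMatrix", function(x, ...) x@panel)
#' @rdname dplsr-generics
#' @export
setMethod("measurementMatrix", "NormalizedMatrix", function(x, ...) x@matrix)

#' @export
#' @rdname dplsr-generics
setMethod("as.matrix", "NormalizedMatrix", function(x, ...) x@matrix)

#' @rdname dplsr-generics
#' @export
setMethod("xScores", "PLSModel", function(object, ...) object@xScores)
#' @rdname dplsr-generics
#' @export
setMethod("xLoadings", "PLSModel", function(object, ...) object@xLoadings)
#' @rdname dplsr-generics
#' @export
setMethod("xWeights", "PLSModel", function(object, ...) object@xWeights)
#' @rdname dplsr-generics
#' @export
setMethod("yLoadings", "PLSModel", function(object, ...) object@yLoadings)
#' @rdname dplsr-generics
#' @export
setMethod("explainedVariance", "PLSModel", function(object, ...)
  object@explainedXVariance)
#' @rdname dplsr-generics
#' @export
setMethod("analyteNames", "PLSModel", function(x, ...) x@analyteNames)

#' @rdname dplsr-generics
#' @export
setMethod("xScores", "RotatedModel", function(object, ...)
  object@base@xScores)
#' @rdname dplsr-generics
#' @export
setMethod("xLoadings", "RotatedModel", function(object, ...)
  object@base@xLoadings)
#' @rdname dplsr-generics
#' @export
setMethod("rotationAngle", "RotatedModel", function(object, ...)
  object@theta)
#' @rdname dplsr-generics
#' @export
setMethod("rotatedScores", "RotatedModel", function(object, ...)
  object@rotatedScores)
#' @rdname dplsr-generics
#' @export
setMethod("rotatedLoadings", "RotatedModel", function(object, ...)
  object@rotatedLoadings)
#' @rdname dplsr-generics
#' @export
setMethod("separationScore", "RotatedModel", function(object, ...)
  object@separationScore)
#' @rdname dplsr-generics
#' @export
setMethod("analyteNames", "RotatedModel", function(x, ...)
  x@base@analyteNames)

#' @rdname dplsr-generics
#' @export
setMethod("analyteNames", "MonteCarloSummary", function(x, ...)
  x@analyteNames)

#' @describeIn MonteCarloSummary-class one row per analyte: `analyte`,
#'   `lv1_mean`, `lv1_sd`, `lv2_mean`, `lv2_sd`, `rank` (LV1-mean
#'   descending, alphabetical tie-break).
#' @param object a `MonteCarloSummary`.
#' @param ... unused.
#' @export
setMethod("mcTable", "MonteCarloSummary", function(object, ...) {
  ord <- rankCorrelates(object)
  rk <- match(object@analyteNames, ord)
  data.frame(analyte = object@analyteNames,
             lv1_mean = object@lv1Mean, lv1_sd = object@lv1Sd,
             lv2_mean = object@lv2Mean, lv2_sd = object@lv2Sd,
             rank = rk, stringsAsFactors = FALSE)
})
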