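#' @include pls.R
NULL

# 2x2 counter-clockwise rotation matrix [[cos, -sin], [sin, cos]].
rotationMatrix <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

#' Welch-style separation criterion
#'
#' Standardized mean difference between the target group's scores and all
#' other samples' scores along one axis:
#' `(m_t - m_o) / sqrt(s_t^2/n_t + s_o^2/n_o)`. When a group has a single
#' member its variance term is taken as 0; if both variance terms vanish
#' the criterion is `+/-Inf` with the sign of the mean difference (0 when
#' the means also coincide). Scale-free, signed: positive when the target
#' lies to the right.
#'
#' @param scores numeric vector (or one-column matrix) of per-sample
#'   scores along the candidate axis.
#' @param isTarget logical vector, `TRUE` for target-condition samples.
#' @return A single numeric criterion value.
#' @export
welchSeparation <- function(scores, isTarget) {
  scores <- as.numeric(scores)
  isTarget <- as.logical(isTarget)
  nT <- sum(isTarget); nO <- sum(!isTarget)
  if (nT == 0 || nO == 0)
    stop("both the target group and its complement must be non-empty")
  mT <- mean(scores[isTarget]); mO <- mean(scores[!isTarget])
  vT <- if (nT > 1) stats::var(scores[isTarget]) else 0
  vO <- if (nO > 1) stats::var(scores[!isTarget]) else 0
  denom <- sqrt(vT / nT + vO / nO)
  if (denom == 0) {
    d <- mT - mO
    return(if (d == 0) 0 else sign(d) * Inf)
  }
  (mT - mO) / denom
}

# Vectorized Welch criterion over the columns of an n x g score matrix.
# Same definition as welchSeparation(), evaluated for every candidate angle
# at once.
.welchColumns <- function(S, isTarget) {
  nT <- sum(isTarget); nO <- sum(!isTarget)
  ST <- S[isTarget, , drop = FALSE]
  SO <- S[!isTarget, , drop = FALSE]
  mT <- colMeans(ST); mO <- colMeans(SO)
  vT <- if (nT > 1) (colSums(ST^2) - nT * mT^2) / (nT - 1) else rep(0, ncol(S))
  vO <- if (nO > 1) (colSums(SO^2) - nO * mO^2) / (nO - 1) else rep(0, ncol(S))
  vT <- pmax(vT, 0); vO <- pmax(vO, 0)
  denom <- sqrt(vT / nT + vO / nO)
  d <- mT - mO
  out <- ifelse(denom > 0, d / denom, ifelse(d == 0, 0, sign(d) * Inf))
  out
}

#' Rotate the LV1-LV2 plane to best separate the target condition
#'
#' Searches a uniform grid of angles `theta` in `[0, 2*pi)` for the
#' orthogonal in-plane rotation whose rotated LV1 scores best separate the
#' design's target condition from all other samples, as measured by
#' `criterion` (default [welchSeparation()]). Scores and loadings of
#' LV1/LV2 are right-multiplied by `[[cos, -sin], [sin, cos]]`; ties are
#' broken toward the smallest angle. Because the criterion is signed and
#' the grid covers the full circle, the maximizer automatically puts the
#' target group's mean on the positive (right) side of rotated LV1.
#'
#' @param model a [PLSModel-class] with at least 2 components.
#' @param design the [DiscriminantDesign-class] the model was fitted to
#'   (supplies target membership).
#' @param gridSize number of candidate angles (default 3600, i.e. 0.1
#'   degree steps).
#' @param criterion function `(scores, isTarget) -> numeric`; pluggable so
#'   alternatives (raw mean difference, silhouette) can be swapped in.
#' @return A [RotatedModel-class].
#' @export
rotateForSeparation <- function(model, design, gridSize = 3600,
                                criterion = welchSeparation) {
  stopifnot(methods::is(model, "PLSModel"),
            methods::is(design, "DiscriminantDesign"))
  if (model@nComponents < 2)
    stop("rotation requires at least 2 latent variables")
  isTarget <- design@indicator[, design@targetCondition] == 1
  if (!any(isTarget) || all(isTarget))
    stop("both the target group and its complement must be non-empty")
  Tm <- model@xScores[, 1:2, drop = FALSE]
  if (sum(Tm^2) == 0 || max(apply(Tm, 2, stats::var)) < 1e-30)
    stop("all scores identical: no direction separates anything")
  gridSize <- as.integer(gridSize)
  thetas <- 2 * pi * (seq_len(gridSize) - 1L) / gridSize

  useFast <- identical(criterion, welchSeparation)
  if (useFast) {
    # rotated LV1 for every grid angle in one matrix product
    S <- Tm %*% rbind(cos(thetas), sin(thetas))
    crit <- .welchColumns(S, isTarget)
  } else {
    crit <- vapply(thetas, function(th)
      criterion((Tm %*% rotationMatrix(th))[, 1], isTarget), numeric(1))
  }
  j <- which.max(crit)  # which.max takes the first maximum: smallest theta
  theta <- thetas[j]
  R <- rotationMatrix(theta)
  rs <- Tm %*% R
  rl <- model@xLoadings[, 1:2, drop = FALSE] %*% R
  colnames(rs) <- colnames(rl) <- c("LV1", "LV2")
  methods::new("RotatedModel", base = model, theta = theta,
               rotatedScores = rs, rotatedLoadings = rl,
               separationScore = crit[j],
               targetCondition = design@targetCondition)
}

#' Export a rotated model as JSON
#'
#' Writes condition order, the rotation angle (radians and degrees),
#' per-analyte rotated LV1/LV2 loadings, per-sample rotated scores,
#' explained X variance and convergence flags to a JSON document.
#'
#' @param model a [RotatedModel-class].
#' @param path output file path.
#' @param conditions optional per-sample condition labels to embed with the
#'   scores.
#' @return `path`, invisibly.
#' @export
writeModelJSON <- function(model, path, conditions = NULL) {
  stopifnot(methods::is(model, "RotatedModel"))
  rs <- rotatedScores(model)
  rl <- rotatedLoadings(model)
  doc <- list(
    condition_order = rownames(model@base@yLoadings),
    target_condition = model@targetCondition,
    theta_radians = model@theta,
    theta_degrees = model@theta * 180 / pi,
    separation_score = model@separationScore,
    explained_x_variance = model@base@explainedXVariance,
    converged = model@base@converged,
    loadings = data.frame(analyte = analyteNames(model),
                          lv1 = rl[, 1], lv2 = rl[, 2]),
    scores = data.frame(sample_id = rownames(rs),
                        condition = if (is.null(conditions)) NA else conditions,
                        lv1 = rs[, 1], lv2 = rs[, 2]))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}
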