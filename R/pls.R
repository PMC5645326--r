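#' @include AllClasses.R
NULL

#' Encode condition labels as a discriminant response
#'
#' Builds the response block for a discriminant PLS regression: a one-hot
#' indicator over all conditions (columns in first-appearance order of
#' `conditions`, or in an explicit `conditionOrder`) and a column-centered
#' copy. All conditions enter the response — the model segregates every
#' group simultaneously — and the target condition is only used later, by
#' the rotation stage. The indicator is centered but not variance-scaled.
#'
#' @param conditions character vector of per-sample condition labels.
#' @param targetCondition the condition the rotation stage will separate;
#'   must occur among `conditions`.
#' @param conditionOrder optional explicit column order (used when refitting
#'   on subsamples so columns stay comparable to the total model).
#' @return A [DiscriminantDesign-class].
#' @examples
#' encodeDiscriminant(c("A", "A", "B"), targetCondition = "B")
#' @export
encodeDiscriminant <- function(conditions, targetCondition,
                               conditionOrder = NULL) {
  conditions <- as.character(conditions)
  if (length(conditions) < 2)
    stop("at least 2 samples are required")
  if (is.null(conditionOrder))
    conditionOrder <- unique(conditions)
  if (length(unique(conditions)) < 2)
    stop("degenerate design: only one distinct condition")
  if (!all(conditions %in% conditionOrder))
    stop("conditions outside conditionOrder: ",
         paste(setdiff(conditions, conditionOrder), collapse = ", "))
  if (!targetCondition %in% conditions)
    stop("target condition '", targetCondition,
         "' not present among the samples")
  ind <- outer(conditions, conditionOrder, "==") * 1
  dimnames(ind) <- list(names(conditions), conditionOrder)
  centered <- sweep(ind, 2, colMeans(ind), "-")
  methods::new("DiscriminantDesign", conditionOrder = conditionOrder,
               indicator = ind, centered = centered,
               targetCondition = targetCondition)
}

#' Fit a discriminant PLS model by NIPALS
#'
#' Two-block NIPALS: for each latent variable the X-weight, X-score,
#' Y-loading and Y-score vectors are updated alternately until the weight
#' vector changes by less than `tol` (or `maxIter` is reached, in which
#' case the component is flagged as unconverged but kept). After each
#' component, X is deflated by the rank-one score-loading outer product and
#' Y by the score/Y-loading product. The Y-score is initialized from the
#' response column with the largest sum of squares, making the fit
#' deterministic.
#'
#' For a single centered response this reduces in one step to the classical
#' direction `w = X'y / ||X'y||`, and for a multivariate response the first
#' weight vector converges to the dominant left singular vector of `X'Y`.
#'
#' @param X numeric `n x p` matrix, or a [NormalizedMatrix-class]. Expected
#'   column-centered (z-scored upstream); enforced when
#'   `checkCentered = TRUE`.
#' @param design a [DiscriminantDesign-class] (the centered indicator is
#'   used as the response block), or a centered numeric response vector or
#'   matrix for plain two-block PLS regression.
#' @param nComponents number of latent variables (default 2; must satisfy
#'   `nComponents <= min(n - 1, p)`).
#' @param tol convergence tolerance on the change of the weight vector
#'   (default 1e-10).
#' @param maxIter iteration cap per component (default 1000).
#' @param checkCentered verify `|column mean| < 1e-8` before fitting.
#'   Subsample refits inherit the full-data z-scoring and are only
#'   approximately centered, so the Monte Carlo path disables this check.
#' @return A [PLSModel-class].
#' @examples
#' nm <- zscoreColumns(generatePanel(syntheticConfig(seed = 7), "phospho")$table)
#' d <- encodeDiscriminant(sampleConditions(nm), "hypoxia_bFGF")
#' fitPLS(nm, d)
#' @export
fitPLS <- function(X, design, nComponents = 2, tol = 1e-10, maxIter = 1000,
                   checkCentered = TRUE) {
  if (methods::is(X, "NormalizedMatrix")) X <- X@matrix
  X <- as.matrix(X)
  if (!all(is.finite(X)))
    stop("X contains non-finite entries")
  if (is.numeric(design)) {
    Y <- as.matrix(design)
    condNames <- colnames(Y)
    if (is.null(condNames)) condNames <- paste0("y", seq_len(ncol(Y)))
  } else {
    stopifnot(methods::is(design, "DiscriminantDesign"))
    Y <- design@centered
    condNames <- design@conditionOrder
  }
  if (nrow(Y) != nrow(X))
    stop("design and X disagree on the number of samples")
  n <- nrow(X); p <- ncol(X)
  A <- as.integer(nComponents)
  if (A < 1 || A > min(n - 1, p))
    stop("nComponents must be between 1 and min(n - 1, p) = ",
         min(n - 1, p))
  if (checkCentered && any(abs(colMeans(X)) >= 1e-8))
    stop("X must be column-centered (z-score upstream)")
  analytes <- colnames(X)
  if (is.null(analytes)) analytes <- paste0("analyte_", seq_len(p))

  totvar <- sum(X^2)
  W <- P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  Q <- matrix(0, ncol(Y), A)
  converged <- logical(A)
  iters <- integer(A)
  for (a in seq_len(A)) {
    u <- Y[, which.max(colSums(Y^2))]
    w <- rep(0, p)
    for (it in seq_len(maxIter)) {
      wNew <- crossprod(X, u)[, 1]
      nw <- sqrt(sum(wNew^2))
      if (nw == 0)
        stop("degenerate component ", a, ": X'u vanished")
      wNew <- wNew / nw
      tv <- X %*% wNew
      q <- crossprod(Y, tv)[, 1] / sum(tv^2)
      u <- (Y %*% q)[, 1] / sum(q^2)
      delta <- sqrt(sum((wNew - w)^2))
      w <- wNew
      if (delta < tol) { converged[a] <- TRUE; break }
    }
    iters[a] <- it
    tv <- (X %*% w)[, 1]
    pv <- crossprod(X, tv)[, 1] / sum(tv^2)
    W[, a] <- w
    Tm[, a] <- tv
    P[, a] <- pv
    Q[, a] <- crossprod(Y, tv)[, 1] / sum(tv^2)
    X <- X - tcrossprod(tv, pv)
    Y <- Y - tcrossprod(tv, Q[, a])
  }
  explained <- colSums(Tm^2) * colSums(P^2) / totvar
  dimnames(W) <- dimnames(P) <- list(analytes, paste0("LV", seq_len(A)))
  dimnames(Tm) <- list(rownames(X), paste0("LV", seq_len(A)))
  dimnames(Q) <- list(condNames, paste0("LV", seq_len(A)))
  methods::new("PLSModel", nComponents = A, xWeights = W, xLoadings = P,
               xScores = Tm, yLoadings = Q, converged = converged,
               iterationsUsed = iters, explainedXVariance = explained,
               analyteNames = analytes)
}
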