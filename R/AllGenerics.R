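#' @include dplsr-package.R
NULL

#' Accessor generics for dplsr classes
#'
#' Small accessor generics used across the package's S4 classes. Each has a
#' method on the class that owns the quantity; see the class pages for
#' details.
#'
#' @param x,object an object of one of the package's S4 classes.
#' @param ... further arguments passed to methods.
#' @return The requested component (a matrix, vector or scalar; see methods).
#' @name dplsr-generics
#' @rdname dplsr-generics
NULL

#' @rdname dplsr-generics
#' @export
setGeneric("analyteNames", function(x, ...) standardGeneric("analyteNames"))

#' @rdname dplsr-generics
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname dplsr-generics
#' @export
setGeneric("sampleConditions", function(x, ...) standardGeneric("sampleConditions"))

#' @rdname dplsr-generics
#' @export
setGeneric("totalProtein", function(x, ...) standardGeneric("totalProtein"))

#' @rdname dplsr-generics
#' @export
setGeneric("panelType", function(x, ...) standardGeneric("panelType"))

#' @rdname dplsr-generics
#' @export
setGeneric("measurementMatrix", function(x, ...) standardGeneric("measurementMatrix"))

#' @rdname dplsr-generics
#' @export
setGeneric("xScores", function(object, ...) standardGeneric("xScores"))

#' @rdname dplsr-generics
#' @export
setGeneric("xLoadings", function(object, ...) standardGeneric("xLoadings"))

#' @rdname dplsr-generics
#' @export
setGeneric("xWeights", function(object, ...) standardGeneric("xWeights"))

#' @rdname dplsr-generics
#' @export
setGeneric("yLoadings", function(object, ...) standardGeneric("yLoadings"))

#' @rdname dplsr-generics
#' @export
setGeneric("explainedVariance", function(object, ...) standardGeneric("explainedVariance"))

#' @rdname dplsr-generics
#' @export
setGeneric("rotationAngle", function(object, ...) standardGeneric("rotationAngle"))

#' @rdname dplsr-generics
#' @export
setGeneric("rotatedScores", function(object, ...) standardGeneric("rotatedScores"))

#' @rdname dplsr-generics
#' @export
setGeneric("rotatedLoadings", function(object, ...) standardGeneric("rotatedLoadings"))

#' @rdname dplsr-generics
#' @export
setGeneric("separationScore", function(object, ...) standardGeneric("separationScore"))

#' @rdname dplsr-generics
#' @export
setGeneric("mcTable", function(object, ...) standardGeneric("mcTable"))
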