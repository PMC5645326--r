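#' @include AllClasses.R
NULL

#' Read a sample-by-analyte table from delimited text
#'
#' Reads a CSV or TSV file (delimiter chosen from the file extension) with a
#' header row containing `sample_id`, `condition`, `total_protein`, and one
#' column per analyte in file order, and returns a validated
#' [AnalyteExperiment-class]. Row order and analyte order are preserved.
#'
#' @param path path to a `.csv` or `.tsv`/`.txt` file (UTF-8).
#' @param panel `"cytokine"` or `"phospho"`; stored with the object.
#' @return An [AnalyteExperiment-class] in raw units.
#' @details Validation is strict: a missing required column is a format
#'   error naming the column; a negative measurement or non-positive total
#'   protein is a validation error naming the sample (and analyte); a
#'   duplicated `sample_id` or missing entry is rejected. Missing values are
#'   never imputed — silent imputation would change loadings invisibly.
#' @seealso [normalizeTotalProtein()], [zscoreColumns()]
#' @export
readAnalyteTable <- function(path, panel = c("cytokine", "phospho")) {
  panel <- match.arg(panel)
  if (!file.exists(path))
    stop("file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  required <- c("sample_id", "condition", "total_protein")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("format error: required column(s) missing: ",
         paste(missing, collapse = ", "))
  analytes <- setdiff(colnames(df), required)
  if (!length(analytes))
    stop("format error: no analyte columns found")
  if (anyDuplicated(df$sample_id))
    stop("validation error: duplicate sample_id: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  vals <- as.matrix(df[, analytes, drop = FALSE])
  storage.mode(vals) <- "double"
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("validation error: missing value for sample '",
         df$sample_id[bad[1]], "', analyte '", analytes[bad[2]], "'")
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("validation error: negative measurement for sample '",
         df$sample_id[bad[1]], "', analyte '", analytes[bad[2]], "'")
  }
  tp <- as.numeric(df$total_protein)
  if (anyNA(tp) || any(tp <= 0)) {
    bad <- df$sample_id[which(is.na(tp) | tp <= 0)]
    stop("validation error: non-positive total_protein for sample(s): ",
         paste(bad, collapse = ", "))
  }
  AnalyteExperiment(vals, sampleIds = df$sample_id,
                    conditions = df$condition, totalProtein = tp,
                    panel = panel, analyteNames = analytes)
}

#' Normalize measurements to total protein
#'
#' Divides every sample's measurements by that sample's total protein
#' content, correcting for the different cell numbers produced by the
#' different proliferation rates across culture conditions. Units become
#' measurement-per-microgram; the `total_protein` column is retained for
#' audit and the object's stage is advanced to `"protein_normalized"`.
#'
#' @param x an [AnalyteExperiment-class] (raw stage).
#' @return An [AnalyteExperiment-class] with normalized values.
#' @export
normalizeTotalProtein <- function(x) {
  stopifnot(methods::is(x, "AnalyteExperiment"))
  if (identical(S4Vectors::metadata(x)$stage, "protein_normalized"))
    warning("object is already protein-normalized; normalizing again")
  a <- SummarizedExperiment::assay(x, "exprs")
  tp <- totalProtein(x)
  SummarizedExperiment::assay(x, "exprs") <- sweep(a, 2, tp, "/")
  S4Vectors::metadata(x)$stage <- "protein_normalized"
  methods::validObject(x)
  x
}

#' Z-score each analyte column
#'
#' Standardizes every analyte across samples to mean 0, SD 1 (sample
#' standard deviation, `n - 1` denominator), returning a
#' [NormalizedMatrix-class] ready for PLS modeling. The removed column
#' means and SDs are recorded so either standardization convention can be
#' audited or the transform inverted.
#'
#' @param x an [AnalyteExperiment-class]; typically protein-normalized
#'   first (see [normalizeTotalProtein()]).
#' @param onZeroVariance `"error"` (default) stops, naming the constant
#'   analyte; `"drop"` removes such columns with a warning.
#' @return A [NormalizedMatrix-class].
#' @examples
#' v <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), 4, 2,
#'             dimnames = list(paste0("s", 1:4), c("a", "b")))
#' ae <- AnalyteExperiment(v, rownames(v), c("A", "A", "B", "B"),
#'                         totalProtein = rep(1, 4), panel = "cytokine")
#' zscoreColumns(ae)
#' @export
zscoreColumns <- function(x, onZeroVariance = c("error", "drop")) {
  stopifnot(methods::is(x, "AnalyteExperiment"))
  onZeroVariance <- match.arg(onZeroVariance)
  m <- measurementMatrix(x)
  mu <- colMeans(m)
  sdev <- apply(m, 2, stats::sd)
  zero <- sdev == 0 | !is.finite(sdev)
  if (any(zero)) {
    if (onZeroVariance == "error")
      stop("zero-variance analyte column(s): ",
           paste(colnames(m)[zero], collapse = ", "))
    warning("dropping zero-variance analyte column(s): ",
            paste(colnames(m)[zero], collapse = ", "))
    m <- m[, !zero, drop = FALSE]
    mu <- mu[!zero]
    sdev <- sdev[!zero]
  }
  z <- sweep(sweep(m, 2, mu, "-"), 2, sdev, "/")
  methods::new("NormalizedMatrix", matrix = z,
               conditions = sampleConditions(x),
               columnMeans = unname(mu), columnSds = unname(sdev),
               panel = panelType(x))
}

#' Write a normalized matrix and its z-scoring sidecar
#'
#' Writes the z-scored matrix as delimited text (same layout the ingest
#' reads: `sample_id`, `condition`, then analytes) and a JSON sidecar
#' (`<path>.json`) recording the column means/SDs removed by z-scoring and
#' the panel, so the output is auditable and round-trippable.
#'
#' @param x a [NormalizedMatrix-class].
#' @param path output file; `.csv` writes comma-separated, otherwise tabs.
#' @return `path`, invisibly.
#' @export
writeNormalizedMatrix <- function(x, path) {
  stopifnot(methods::is(x, "NormalizedMatrix"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- data.frame(sample_id = sampleIds(x), condition = x@conditions,
                   x@matrix, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  sidecar <- list(panel = x@panel,
                  analytes = analyteNames(x),
                  column_means = x@columnMeans,
                  column_sds = x@columnSds,
                  sd_denominator = "n-1")
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
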