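#' @include pipeline.R
#' @importFrom rlang .data
NULL

#' Scores scatter for one panel
#'
#' Rotated LV1 vs LV2, one color/shape per condition — the
#' condition-separation view in which the target condition clusters to the
#' right.
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param panel which panel to draw.
#' @return A ggplot object.
#' @export
plotScores <- function(report, panel = c("cytokine", "phospho")) {
  panel <- match.arg(panel)
  st <- report[[panel]]$scoresTable
  ev <- 100 * explainedVariance(report[[panel]]$model@base)
  ggplot2::ggplot(st, ggplot2::aes(x = .data$lv1, y = .data$lv2,
                                   color = .data$condition,
                                   shape = .data$condition)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.2, color = "grey70") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(
      x = sprintf("LV1 (%.1f%% of X variance)", ev[1]),
      y = sprintf("LV2 (%.1f%% of X variance)", ev[2]),
      title = sprintf("%s panel: rotated LV1-LV2 scores", panel)) +
    ggplot2::theme_bw()
}

#' Sorted loading bar chart with Monte Carlo error bars
#'
#' Mean rotated-LV1 loading per analyte, most positive (strongest target
#' correlate) first, with symmetric SD error bars from the subsampling
#' iterations. Zero-length bars (e.g. from a subsample fraction of 1)
#' render without error.
#'
#' @inheritParams plotScores
#' @param lv which latent variable to draw (1 or 2).
#' @return A ggplot object.
#' @export
plotLoadings <- function(report, panel = c("cytokine", "phospho"), lv = 1) {
  panel <- match.arg(panel)
  lt <- report[[panel]]$loadingsTable
  mcol <- if (lv == 1) "lv1_mean" else "lv2_mean"
  scol <- if (lv == 1) "lv1_sd" else "lv2_sd"
  lt$analyte <- factor(lt$analyte,
                       levels = lt$analyte[order(-lt[[mcol]], lt$analyte)])
  ggplot2::ggplot(lt, ggplot2::aes(x = .data$analyte, y = .data[[mcol]])) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data[[mcol]] - .data[[scol]],
                                        ymax = .data[[mcol]] + .data[[scol]]),
                           width = 0.3, linewidth = 0.3) +
    ggplot2::labs(x = NULL, y = sprintf("LV%d loading (mean ± SD)", lv),
                  title = sprintf("%s panel: rotated LV%d loadings", panel,
                                  lv)) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60,
                                                       hjust = 1, size = 7))
}

#' Render all report figures to disk
#'
#' For each panel: the scores scatter and the sorted LV1 loading bar
#' chart, each in a vector format (SVG where the cairo device is
#' available, PDF otherwise) and raster PNG.
#'
#' @param report a `RunReport` from [runPipeline()].
#' @param outputDir directory, created on demand.
#' @return Character vector of files written, invisibly.
#' @export
renderPlots <- function(report, outputDir) {
  stopifnot(inherits(report, "RunReport"))
  if (!dir.exists(outputDir)) {
    ok <- dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outputDir))
      stop("cannot create output directory: ", outputDir)
  }
  vectorExt <- if (isTRUE(capabilities("cairo")[[1]])) "svg" else "pdf"
  files <- character()
  for (pn in report$manifest$panels) {
    wide <- max(6, 0.22 * nrow(report[[pn]]$loadingsTable) + 2)
    figs <- list(scores = list(plotScores(report, pn), 6, 4.5),
                 loadings = list(plotLoadings(report, pn), wide, 4))
    for (nm in names(figs)) {
      for (ext in c(vectorExt, "png")) {
        f <- file.path(outputDir, sprintf("%s_%s.%s", nm, pn, ext))
        dev <- if (ext == "svg") grDevices::svg else ext
        ggplot2::ggsave(f, figs[[nm]][[1]], device = dev,
                        width = figs[[nm]][[2]], height = figs[[nm]][[3]],
                        dpi = 150)
        files <- c(files, f)
      }
    }
  }
  invisible(files)
}
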