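#' Run a complete scoring analysis from files on disk
#'
#' Orchestrates read -> (optional normalize) -> panel restriction ->
#' fold-changes -> SPIA -> dataset summaries -> CDEI -> ranking, and writes
#' `report.tsv` (the human-readable table), `summary.txt` (full-precision
#' key-value audit record) and `scores.tsv` (the long pathway x sample
#' score table) into `outDir`. On error, partial outputs are removed.
#'
#' @param expression Path to the expression TSV (see [readExpression()]).
#' @param design Path to the design CSV (see [readDesign()]).
#' @param pathways Path to the signed edge-list TSV (see [readPathways()]).
#' @param genePanel Optional path to a gene-panel file.
#' @param normalize Logical; treat the input as raw counts and apply
#'   median-of-ratios normalization first.
#' @param pseudocount Pseudocount for the fold-changes; default 1.
#' @param outDir Output directory (created if needed).
#' @return The [CdeiResult-class], invisibly.
#' @export
runScore <- function(expression, design, pathways, genePanel = NULL,
                     normalize = FALSE, pseudocount = 1,
                     outDir = ".") {
  written <- character()
  ok <- FALSE
  on.exit(if (!ok) unlink(written), add = TRUE)

  exprs <- readExpression(expression)
  des <- readDesign(design)
  lib <- readPathways(pathways)
  if (!length(lib))
    stop("pathway file contains no pathways: ", pathways, call. = FALSE)
  panel <- if (!is.null(genePanel)) readGenePanel(genePanel) else NULL
  if (normalize) exprs <- normalizeCounts(exprs)
  x <- CdeiExperiment(exprs, des)
  res <- cdei(x, lib, panel = panel, pseudocount = pseudocount)

  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  written <- file.path(outDir, c("report.tsv", "summary.txt", "scores.tsv"))
  writeCdeiReport(res, written[1L])
  writeRunSummary(res, written[2L])
  # score table is recomputed for the audit trail (identical pathway set)
  sc <- scorePathways(
    if (is.null(panel)) x else {
      cd <- SummarizedExperiment::colData(x)
      CdeiExperiment(
        restrictToPanel(SummarizedExperiment::assay(x, "exprs"), panel),
        data.frame(sample = rownames(cd),
                   condition = as.character(cd$condition),
                   drug = as.character(cd$drug)))
    },
    lib, pseudocount = pseudocount)
  writeScoreTable(sc$scores, written[3L])
  ok <- TRUE
  invisible(res)
}

#' Generate and write a complete synthetic dataset
#'
#' Writes `expression.tsv`, `design.csv`, `pathways.tsv`, `panel.txt`
#' (all simulated genes) and `truth.tsv` into `outDir`, in the same
#' dialects [runScore()] consumes, so a simulated directory is immediately
#' scoreable.
#'
#' @param config A [simulationConfig()].
#' @param outDir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
runSimulate <- function(config, outDir = ".") {
  stopifnot(inherits(config, "SimulationConfig"))
  lib <- simulatePathways(config)
  sim <- simulateDataset(config, lib)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- c(expression = file.path(outDir, "expression.tsv"),
             design = file.path(outDir, "design.csv"),
             pathways = file.path(outDir, "pathways.tsv"),
             panel = file.path(outDir, "panel.txt"),
             truth = file.path(outDir, "truth.tsv"))
  writeExpression(sim$exprs, paths["expression"])
  writeDesign(sim$design, paths["design"])
  writePathways(lib, paths["pathways"])
  writeLines(rownames(sim$exprs), paths["panel"])
  writeGroundTruth(sim$truth, paths["truth"])
  invisible(paths)
}
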