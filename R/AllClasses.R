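#' Pathway: a signed directed gene-interaction graph
#'
#' A `Pathway` holds one signaling pathway as a signed directed graph
#' G(V, E): an ordered set of unique gene symbols (the nodes) and a list of
#' directed edges, each carrying a sign (+1 for activation, -1 for
#' inhibition). Gene order is fixed at construction and used consistently for
#' every derived vector and matrix.
#'
#' @slot id Character scalar, short pathway identifier.
#' @slot name Character scalar, free-text pathway name.
#' @slot genes Character vector of unique gene symbols (ordered node set).
#' @slot edges A `data.frame` with columns `from`, `to` (gene symbols) and
#'   `sign` (+1 or -1). May have zero rows.
#'
#' @seealso [readPathways()], [betaMatrix()], [validatePathway()]
#' @export
setClass("Pathway",
  representation(
    id    = "character",
    name  = "character",
    genes = "character",
    edges = "data.frame"
  )
)

setValidity("Pathway", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@genes) < 1L)
    msg <- c(msg, "a pathway must contain at least one gene")
  if (anyDuplicated(object@genes))
    msg <- c(msg, "gene symbols must be unique within a pathway")
  e <- object@edges
  if (!all(c("from", "to", "sign") %in% names(e))) {
    msg <- c(msg, "'edges' must have columns from, to, sign")
  } else if (nrow(e) > 0L) {
    if (!all(e$from %in% object@genes) || !all(e$to %in% object@genes))
      msg <- c(msg, "every edge endpoint must be a pathway gene")
    if (!all(e$sign %in% c(-1, 1)))
      msg <- c(msg, "edge signs must be +1 or -1")
    if (anyDuplicated(paste0(e$from, "\r", e$to)))
      msg <- c(msg, "duplicate (source, target) edge")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Pathway
#'
#' @param id Short pathway identifier.
#' @param genes Ordered character vector of unique gene symbols. If missing,
#'   the union of edge endpoints in first-seen order.
#' @param edges A `data.frame` with columns `from`, `to`, `sign` (+1/-1);
#'   defaults to no edges.
#' @param name Free-text name; defaults to `id`.
#'
#' @return A [Pathway-class] object.
#' @examples
#' p <- Pathway("P1", edges = data.frame(
#'   from = "A", to = c("B", "C"), sign = c(1, -1)))
#' nGenes(p)
#' @export
Pathway <- function(id, genes = NULL, edges = NULL, name = id) {
  if (is.null(edges))
    edges <- data.frame(from = character(), to = character(),
                        sign = numeric())
  edges <- as.data.frame(edges)[, c("from", "to", "sign")]
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$sign <- as.numeric(edges$sign)
  rownames(edges) <- NULL
  if (is.null(genes)) {
    genes <- unique(as.vector(rbind(edges$from, edges$to)))
  }
  new("Pathway", id = as.character(id), name = as.character(name),
      genes = as.character(genes), edges = edges)
}

#' BetaMatrix: out-degree-normalized signed influence matrix
#'
#' Entry (i, j) is beta_ij / n_down(g_j) when gene j has a declared edge to
#' gene i (beta_ij the edge sign), and 0 otherwise; n_down(g_j) is gene j's
#' out-degree. Columns of genes with zero out-degree are all zero. This is
#' the matrix B of the SPIA closed form Acc = B (I - B)^-1 deltaE.
#'
#' @slot pathwayId Identifier of the source pathway.
#' @slot genes Gene ordering used for rows and columns.
#' @slot nDown Named integer vector of out-degrees.
#' @slot entries The n x n numeric matrix.
#'
#' @seealso [betaMatrix()], [pathwayAccuracies()]
#' @export
setClass("BetaMatrix",
  representation(
    pathwayId = "character",
    genes     = "character",
    nDown     = "integer",
    entries   = "matrix"
  )
)

#' CdeiExperiment: expression matrix plus three-condition sample design
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] whose
#' single assay `exprs` holds nonnegative normalized expression (genes x
#' samples) and whose `colData` assigns every sample to one of three
#' conditions: `control`, `untreated` (pathological state before treatment)
#' or `treated` (with a `drug` label naming the treatment). At least two
#' control samples are required because fold-changes are taken against the
#' control-pool mean.
#'
#' @seealso [CdeiExperiment()], [deltaE()], [scorePathways()]
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("CdeiExperiment", contains = "SummarizedExperiment")

setValidity("CdeiExperiment", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("condition", "drug") %in% colnames(cd)))
    return("colData must contain 'condition' and 'drug'")
  cond <- as.character(cd$condition)
  if (!all(cond %in% c("control", "untreated", "treated")))
    msg <- c(msg, "conditions must be control, untreated or treated")
  if (sum(cond == "control") < 2L)
    msg <- c(msg, "at least two control samples are required (control pool)")
  drug <- as.character(cd$drug)
  if (any(cond == "treated" & (is.na(drug) | !nzchar(drug))))
    msg <- c(msg, "every treated sample needs a drug label")
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (anyNA(x) || any(!is.finite(x)))
      msg <- c(msg, "expression values must be finite")
    else if (any(x < 0))
      msg <- c(msg, "expression values must be nonnegative")
    if (anyDuplicated(rownames(x)))
      msg <- c(msg, "duplicate gene identifiers")
    if (anyDuplicated(colnames(x)))
      msg <- c(msg, "duplicate sample identifiers")
  }
  if (length(msg)) msg else TRUE
})

#' CdeiResult: dataset t statistics, drug efficiency indices and ranking
#'
#' End-to-end result container. `tstats` holds one row per case dataset
#' (the untreated pool and each drug) with the one-sample t statistic of its
#' per-pathway weighted mean SPIA scores against zero; `ranking` holds one
#' row per drug with the efficiency index
#' CDEI = 2(|t_U|/(|t_T|+|t_U|) - 0.5) and the rank; `summaries` keeps the
#' per-pathway weighted means behind each t; `exclusions` lists pathways
#' dropped because (I - B) was numerically singular.
#'
#' @slot tstats `data.frame` with columns `dataset`, `sample_class`,
#'   `n_profiles`, `t_value`, `p_value`, `df`.
#' @slot ranking `data.frame` with columns `drug`, `abs_t_untreated`,
#'   `abs_t_treated`, `cdei`, `rank`.
#' @slot summaries Named list (per dataset) of per-pathway summary
#'   `data.frame`s (`pathway_id`, `mean_score`, `weight`, `spia_mu`).
#' @slot exclusions Character vector of excluded pathway ids.
#' @slot nPathways Integer, number of pathways retained (df + 1).
#'
#' @seealso [cdei()], [cdeiRanking()], [datasetTStats()]
#' @export
setClass("CdeiResult",
  representation(
    tstats     = "data.frame",
    ranking    = "data.frame",
    summaries  = "list",
    exclusions = "character",
    nPathways  = "integer"
  )
)
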