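#' @name accessors
#' @title Accessors for cdei classes
#' @param object A cdei object.
#' @description Small accessor generics so downstream code never touches
#'   slots directly.
NULL

#' @rdname accessors
#' @export
setGeneric("pathwayId", function(object) standardGeneric("pathwayId"))

#' @rdname accessors
#' @export
setGeneric("pathwayGenes", function(object) standardGeneric("pathwayGenes"))

#' @rdname accessors
#' @export
setGeneric("pathwayEdges", function(object) standardGeneric("pathwayEdges"))

#' @rdname accessors
#' @export
setGeneric("nGenes", function(object) standardGeneric("nGenes"))

#' @rdname accessors
#' @export
setGeneric("nDown", function(object) standardGeneric("nDown"))

#' @rdname accessors
#' @export
setGeneric("betaEntries", function(object) standardGeneric("betaEntries"))

#' @rdname accessors
#' @export
setGeneric("cdeiRanking", function(object) standardGeneric("cdeiRanking"))

#' @rdname accessors
#' @export
setGeneric("datasetTStats", function(object) standardGeneric("datasetTStats"))

#' @rdname accessors
#' @export
setGeneric("pathwaySummaries",
           function(object) standardGeneric("pathwaySummaries"))

#' @rdname accessors
#' @export
setGeneric("pathwayExclusions",
           function(object) standardGeneric("pathwayExclusions"))

#' @rdname accessors
#' @export
setMethod("pathwayId", "Pathway", function(object) object@id)

#' @rdname accessors
#' @export
setMethod("pathwayGenes", "Pathway", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("pathwayEdges", "Pathway", function(object) object@edges)

#' @rdname accessors
#' @export
setMethod("nGenes", "Pathway", function(object) length(object@genes))

#' @rdname accessors
#' @export
setMethod("pathwayId", "BetaMatrix", function(object) object@pathwayId)

#' @rdname accessors
#' @export
setMethod("pathwayGenes", "BetaMatrix", function(object) object@genes)

#' @rdname accessors
#' @export
setMethod("nDown", "BetaMatrix", function(object) object@nDown)

#' @rdname accessors
#' @export
setMethod("betaEntries", "BetaMatrix", function(object) object@entries)

#' @rdname accessors
#' @export
setMethod("cdeiRanking", "CdeiResult", function(object) object@ranking)

#' @rdname accessors
#' @export
setMethod("datasetTStats", "CdeiResult", function(object) object@tstats)

#' @rdname accessors
#' @export
setMethod("pathwaySummaries", "CdeiResult", function(object) object@summaries)

#' @rdname accessors
#' @export
setMethod("pathwayExclusions", "CdeiResult",
          function(object) object@exclusions)

#' @describeIn accessors Samples of a `CdeiExperiment` in a given condition.
#' @param x A [CdeiExperiment-class].
#' @param condition One of `"control"`, `"untreated"`, `"treated"`.
#' @export
conditionSamples <- function(x, condition) {
  stopifnot(is(x, "CdeiExperiment"))
  cd <- SummarizedExperiment::colData(x)
  colnames(x)[as.character(cd$condition) == condition]
}

#' @describeIn accessors Distinct drug labels of the treated samples, in
#'   design order.
#' @export
drugLabels <- function(x) {
  stopifnot(is(x, "CdeiExperiment"))
  cd <- SummarizedExperiment::colData(x)
  unique(as.character(cd$drug)[as.character(cd$condition) == "treated"])
}

#' @describeIn accessors Samples treated with one drug.
#' @param drug Drug label.
#' @export
drugSamples <- function(x, drug) {
  stopifnot(is(x, "CdeiExperiment"))
  cd <- SummarizedExperiment::colData(x)
  colnames(x)[as.character(cd$condition) == "treated" &
                as.character(cd$drug) == drug]
}

setMethod("show", "Pathway", function(object) {
  cat("Pathway '", object@id, "' (", object@name, "): ",
      length(object@genes), " genes, ", nrow(object@edges), " edges (",
      sum(object@edges$sign > 0), " activating, ",
      sum(object@edges$sign < 0), " inhibiting)\n", sep = "")
})

setMethod("show", "BetaMatrix", function(object) {
  cat("BetaMatrix for pathway '", object@pathwayId, "': ",
      length(object@genes), " x ", length(object@genes),
      ", nonzero entries: ", sum(object@entries != 0), "\n", sep = "")
})

setMethod("show", "CdeiExperiment", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cond <- as.character(cd$condition)
  cat("CdeiExperiment: ", nrow(object), " genes x ", ncol(object),
      " samples\n", sep = "")
  cat("  control: ", sum(cond == "control"),
      "  untreated: ", sum(cond == "untreated"),
      "  treated: ", sum(cond == "treated"),
      " (", length(drugLabels(object)), " drugs)\n", sep = "")
})

setMethod("show", "CdeiResult", function(object) {
  cat("CdeiResult over", object@nPathways, "pathways",
      sprintf("(df = %d)", object@nPathways - 1L), "\n")
  if (length(object@exclusions))
    cat("  excluded (singular):", paste(object@exclusions, collapse = ", "),
        "\n")
  cat("\n")
  print(reportTable(object), row.names = FALSE)
})
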