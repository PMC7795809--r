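#' Per-gene accuracies and the SPIA score via the matrix closed form
#'
#' Solves the perturbation-factor recursion in closed form:
#' Acc = B (I - B)^-1 deltaE, computed as the linear solve
#' (I - B) y = deltaE followed by Acc = B y, then PF = Acc + deltaE and
#' SPIA = sum(Acc). The sum of accuracies is the pathway perturbation
#' score: positive for an upregulated pathway, negative for a
#' downregulated one.
#'
#' @param beta A [BetaMatrix-class].
#' @param delta Named numeric deltaE vector covering the pathway genes
#'   (names are matched; missing genes are an error).
#' @param tol Reciprocal-condition threshold below which (I - B) is treated
#'   as singular. Default `1e-10`.
#' @return List with elements `pf`, `acc` (named numeric vectors) and
#'   `spiaScore` (scalar sum of `acc`).
#' @examples
#' p <- Pathway("chain", edges = data.frame(from = "A", to = "B", sign = 1))
#' pathwayAccuracies(betaMatrix(p), c(A = 1, B = 0))  # acc = (0, 1)
#' @seealso [pathwayAccuraciesRecursive()] for the direct evaluation of the
#'   recursion on acyclic pathways, [scorePathways()] for the batch driver.
#' @export
pathwayAccuracies <- function(beta, delta, tol = 1e-10) {
  stopifnot(is(beta, "BetaMatrix"))
  g <- pathwayGenes(beta)
  if (!all(g %in% names(delta)))
    stop("deltaE vector is missing pathway genes: ",
         paste(setdiff(g, names(delta)), collapse = ", "), call. = FALSE)
  de <- as.numeric(delta[g])
  B <- betaEntries(beta)
  ImB <- diag(length(g)) - B
  rc <- if (length(g) == 1L) abs(ImB[1L, 1L]) else
    tryCatch(1 / kappa(ImB, exact = FALSE), error = function(e) 0)
  if (!is.finite(rc) || rc <= tol)
    stop(singularPathwayError(pathwayId(beta)))
  y <- solve(ImB, de)
  acc <- as.numeric(B %*% y)
  names(acc) <- g
  pf <- acc + stats::setNames(de, g)
  list(pf = pf, acc = acc, spiaScore = sum(acc))
}

singularPathwayError <- function(pathwayId) {
  structure(
    class = c("cdeiSingularPathway", "error", "condition"),
    list(message = paste0("(I - B) is numerically singular for pathway '",
                          pathwayId, "'"),
         call = NULL, pathwayId = pathwayId)
  )
}

#' Per-gene accuracies by direct evaluation of the recursion
#'
#' Evaluates PF(g) = deltaE(g) + sum over direct upstream regulators gamma
#' of sign(gamma -> g) * PF(gamma) / n_down(gamma), gene by gene in
#' topological order. Only defined for acyclic pathways; serves as the
#' independent oracle for [pathwayAccuracies()].
#'
#' @param pathway A [Pathway-class] (must be acyclic).
#' @param delta Named numeric deltaE vector covering the pathway genes.
#' @return Same structure as [pathwayAccuracies()].
#' @export
pathwayAccuraciesRecursive <- function(pathway, delta) {
  stopifnot(is(pathway, "Pathway"))
  if (!isAcyclic(pathway))
    stop("recursive evaluation requires an acyclic pathway; '",
         pathwayId(pathway), "' has a cycle", call. = FALSE)
  g <- pathwayGenes(pathway)
  if (!all(g %in% names(delta)))
    stop("deltaE vector is missing pathway genes", call. = FALSE)
  e <- pathwayEdges(pathway)
  ndown <- stats::setNames(integer(length(g)), g)
  if (nrow(e)) {
    tb <- table(factor(e$from, levels = g))
    ndown[names(tb)] <- as.integer(tb)
  }
  pf <- stats::setNames(rep(NA_real_, length(g)), g)
  for (gene in topologicalOrder(pathway)) {
    up <- e[e$to == gene, , drop = FALSE]
    contrib <- if (nrow(up))
      sum(up$sign * pf[up$from] / ndown[up$from]) else 0
    pf[gene] <- delta[[gene]] + contrib
  }
  pf <- pf[g]
  acc <- pf - as.numeric(delta[g])
  list(pf = pf, acc = acc, spiaScore = sum(acc))
}

#' Score every pathway for every case sample
#'
#' Computes the SPIA perturbation score of each pathway in each non-control
#' sample. Pathways whose (I - B) is numerically singular are excluded for
#' every sample (so downstream per-dataset vectors share one pathway set)
#' and reported in the `exclusions` element.
#'
#' @param x A [CdeiExperiment-class].
#' @param pathways List of [Pathway-class] objects.
#' @param pseudocount Pseudocount for [deltaE()]; default 1.
#' @param tol Singularity threshold passed to [pathwayAccuracies()].
#' @return List with `scores` (numeric matrix, retained pathways x case
#'   samples) and `exclusions` (character vector of excluded pathway ids).
#' @export
scorePathways <- function(x, pathways, pseudocount = 1, tol = 1e-10) {
  stopifnot(is(x, "CdeiExperiment"), length(pathways) > 0L)
  dem <- deltaEMatrix(x, pseudocount)
  samples <- colnames(dem)
  ids <- vapply(pathways, pathwayId, "")
  scores <- matrix(NA_real_, length(pathways), length(samples),
                   dimnames = list(ids, samples))
  excluded <- character()
  for (k in seq_along(pathways)) {
    p <- pathways[[k]]
    beta <- betaMatrix(p)
    g <- pathwayGenes(p)
    de <- matrix(0, length(g), length(samples),
                 dimnames = list(g, samples))
    hit <- g %in% rownames(dem)
    de[hit, ] <- dem[g[hit], , drop = FALSE]
    ok <- tryCatch({
      for (s in samples) {
        res <- pathwayAccuracies(beta, de[, s], tol = tol)
        scores[k, s] <- res$spiaScore
      }
      TRUE
    }, cdeiSingularPathway = function(e) FALSE)
    if (!ok) excluded <- c(excluded, ids[k])
  }
  keep <- !ids %in% excluded
  if (!any(keep))
    stop("every pathway was excluded as singular; nothing to score",
         call. = FALSE)
  if (length(excluded))
    message("excluded ", length(excluded), " singular pathway(s): ",
            paste(excluded, collapse = ", "))
  list(scores = scores[keep, , drop = FALSE], exclusions = excluded)
}

#' Write a long-format score table
#'
#' TSV with columns `pathway_id`, `sample_id`, `spia_score`.
#'
#' @param scores Pathway x sample score matrix from [scorePathways()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeScoreTable <- function(scores, path) {
  long <- data.frame(
    pathway_id = rep(rownames(scores), times = ncol(scores)),
    sample_id  = rep(colnames(scores), each = nrow(scores)),
    spia_score = as.vector(scores)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
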