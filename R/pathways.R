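#' Read signed pathway topologies from an edge-list file
#'
#' Parses a tab-separated signed edge list into a list of [Pathway-class]
#' objects. The format has a header line
#' `pathway_id<TAB>source<TAB>target<TAB>interaction`, one edge per row,
#' `interaction` either `activation` (+1) or `inhibition` (-1). Lines
#' starting with `#` are ignored. Each distinct `pathway_id` yields one
#' pathway whose gene set is the union of its edge endpoints in first-seen
#' order.
#'
#' @param path Path to the edge-list file.
#' @return Named list of [Pathway-class] objects (possibly empty).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("pathway_id\tsource\ttarget\tinteraction",
#'              "P1\tA\tB\tactivation",
#'              "P1\tA\tC\tinhibition"), f)
#' readPathways(f)
#' @seealso [writePathways()], [betaMatrix()]
#' @export
readPathways <- function(path) {
  if (!file.exists(path))
    stop("pathway file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  lineno <- seq_along(raw)[keep]
  rows <- raw[keep]
  # drop header wherever it sits first
  if (length(rows) && grepl("^pathway_id\t", rows[1L])) {
    lineno <- lineno[-1L]
    rows <- rows[-1L]
  }
  if (!length(rows)) return(list())
  parts <- strsplit(rows, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 4L))
    stop("pathway file ", path, ": line ", lineno[which(nf != 4L)[1L]],
         " does not have 4 tab-separated fields", call. = FALSE)
  tab <- data.frame(
    pathway = vapply(parts, `[`, "", 1L),
    from    = vapply(parts, `[`, "", 2L),
    to      = vapply(parts, `[`, "", 3L),
    type    = vapply(parts, `[`, "", 4L),
    line    = lineno
  )
  bad <- !tab$type %in% c("activation", "inhibition")
  if (any(bad))
    stop("pathway file ", path, ": line ", tab$line[which(bad)[1L]],
         ": unknown interaction '", tab$type[which(bad)[1L]],
         "' (expected activation or inhibition)", call. = FALSE)
  tab$sign <- ifelse(tab$type == "activation", 1, -1)

  key <- paste(tab$pathway, tab$from, tab$to, sep = "\r")
  for (k in unique(key[duplicated(key)])) {
    sg <- unique(tab$sign[key == k])
    ln <- tab$line[key == k]
    if (length(sg) > 1L)
      stop("pathway file ", path, ": lines ", paste(ln, collapse = ", "),
           ": edge declared with conflicting signs", call. = FALSE)
    stop("pathway file ", path, ": lines ", paste(ln, collapse = ", "),
         ": duplicate edge", call. = FALSE)
  }

  out <- lapply(unique(tab$pathway), function(pid) {
    sub <- tab[tab$pathway == pid, , drop = FALSE]
    Pathway(pid, edges = sub[, c("from", "to", "sign")])
  })
  names(out) <- unique(tab$pathway)
  out
}

#' Write pathways back to the signed edge-list dialect
#'
#' Emits the same format [readPathways()] consumes, so load -> write -> load
#' round-trips to identical pathways.
#'
#' @param pathways List of [Pathway-class] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writePathways <- function(pathways, path) {
  lines <- "pathway_id\tsource\ttarget\tinteraction"
  for (p in pathways) {
    e <- pathwayEdges(p)
    if (nrow(e))
      lines <- c(lines, paste(pathwayId(p), e$from, e$to,
                              ifelse(e$sign > 0, "activation", "inhibition"),
                              sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Derive the out-degree-normalized influence matrix B of a pathway
#'
#' Builds the n x n matrix with entry (i, j) = sign(j -> i) / n_down(g_j)
#' for every declared edge j -> i, zero elsewhere; n_down(g_j) is the
#' out-degree of gene j. Genes with no downstream targets get an all-zero
#' column, and the diagonal is zero unless a self-edge is declared
#' explicitly.
#'
#' @param pathway A [Pathway-class].
#' @return A [BetaMatrix-class].
#' @examples
#' p <- Pathway("P1", edges = data.frame(
#'   from = "A", to = c("B", "C"), sign = c(1, -1)))
#' betaEntries(betaMatrix(p))
#' @export
betaMatrix <- function(pathway) {
  stopifnot(is(pathway, "Pathway"))
  g <- pathwayGenes(pathway)
  n <- length(g)
  e <- pathwayEdges(pathway)
  ndown <- integer(n)
  names(ndown) <- g
  if (nrow(e)) {
    tb <- table(factor(e$from, levels = g))
    ndown[names(tb)] <- as.integer(tb)
  }
  B <- matrix(0, n, n, dimnames = list(g, g))
  if (nrow(e)) {
    i <- match(e$to, g)
    j <- match(e$from, g)
    B[cbind(i, j)] <- e$sign / ndown[j]
  }
  new("BetaMatrix", pathwayId = pathwayId(pathway), genes = g,
      nDown = ndown, entries = B)
}

#' Diagnose a pathway before the SPIA linear solve
#'
#' Reports whether (I - B) is numerically invertible (reciprocal condition
#' number above `tol`), whether the pathway graph is acyclic (which makes
#' the recursive evaluation well-defined and guarantees invertibility), and
#' which genes are isolated (no incident edges). A singular matrix is
#' reported, not raised; the scoring layer decides the skip policy.
#'
#' @param pathway A [Pathway-class].
#' @param beta The [BetaMatrix-class] derived from `pathway`; computed if
#'   missing.
#' @param tol Reciprocal-condition threshold below which (I - B) is called
#'   singular. Default `1e-10`.
#' @return List with elements `invertible`, `acyclic`, `isolated` (character
#'   vector) and `rcond` (the reciprocal condition estimate).
#' @export
validatePathway <- function(pathway, beta = betaMatrix(pathway),
                            tol = 1e-10) {
  stopifnot(is(pathway, "Pathway"), is(beta, "BetaMatrix"))
  B <- betaEntries(beta)
  ImB <- diag(nrow(B)) - B
  rc <- if (nrow(B) == 1L) {
    abs(ImB[1L, 1L])
  } else {
    tryCatch(1 / kappa(ImB, exact = FALSE), error = function(e) 0)
  }
  e <- pathwayEdges(pathway)
  touched <- unique(c(e$from, e$to))
  list(
    invertible = is.finite(rc) && rc > tol,
    acyclic    = isAcyclic(pathway),
    isolated   = setdiff(pathwayGenes(pathway), touched),
    rcond      = rc
  )
}

#' @describeIn validatePathway Is the pathway graph acyclic?
#' @export
isAcyclic <- function(pathway) {
  e <- pathwayEdges(pathway)
  if (!nrow(e)) return(TRUE)
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE,
                                     vertices = pathwayGenes(pathway))
  igraph::is_dag(g)
}

# Topological order of the pathway genes (stops on cycles).
topologicalOrder <- function(pathway) {
  e <- pathwayEdges(pathway)
  if (!nrow(e)) return(pathwayGenes(pathway))
  g <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE,
                                     vertices = pathwayGenes(pathway))
  if (!igraph::is_dag(g))
    stop("pathway '", pathwayId(pathway), "' contains a cycle; ",
         "no topological order exists", call. = FALSE)
  names(igraph::topo_sort(g, mode = "out"))
}

#' @describeIn validatePathway Root genes: regulators with downstream
#'   targets but no upstream regulators.
#' @export
rootGenes <- function(pathway) {
  e <- pathwayEdges(pathway)
  if (!nrow(e)) return(character())
  setdiff(unique(e$from), unique(e$to))
}
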