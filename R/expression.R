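#' Read a gene-by-sample expression matrix
#'
#' Reads a TSV whose first column (`gene`) holds gene symbols and whose
#' remaining columns hold one sample each. Values must be finite,
#' nonnegative numbers; gene and sample identifiers must be unique. File
#' order is preserved.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes in rows, samples in columns.
#' @export
readExpression <- function(path) {
  if (!file.exists(path))
    stop("expression file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L)
    stop("expression file ", path, ": need a gene column plus >= 1 sample",
         call. = FALSE)
  genes <- tab[[1L]]
  if (anyDuplicated(genes))
    stop("expression file ", path, ": duplicated gene '",
         genes[anyDuplicated(genes)], "'", call. = FALSE)
  samples <- colnames(tab)[-1L]
  if (anyDuplicated(samples))
    stop("expression file ", path, ": duplicated sample '",
         samples[anyDuplicated(samples)], "'", call. = FALSE)
  m <- matrix(NA_real_, nrow(tab), length(samples),
              dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    v <- suppressWarnings(as.numeric(tab[[j + 1L]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop("expression file ", path, ": non-numeric value '",
           tab[[j + 1L]][i], "' at gene ", genes[i], ", sample ",
           samples[j], call. = FALSE)
    }
    m[, j] <- v
  }
  if (any(!is.finite(m)))
    stop("expression file ", path, ": non-finite values", call. = FALSE)
  if (any(m < 0)) {
    i <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop("expression file ", path, ": negative value at gene ",
         genes[i[1L]], ", sample ", samples[i[2L]], call. = FALSE)
  }
  m
}

#' Write an expression matrix in the dialect readExpression consumes
#'
#' @param m Numeric matrix, genes x samples, with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-design table
#'
#' CSV with header `sample,condition,drug`; `condition` is one of
#' `control`, `untreated`, `treated`; `drug` is non-empty exactly for
#' treated rows.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` with columns `sample`, `condition`, `drug`.
#' @export
readDesign <- function(path) {
  if (!file.exists(path))
    stop("design file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("sample", "condition", "drug")
  if (!all(need %in% colnames(d)))
    stop("design file ", path, ": columns must include ",
         paste(need, collapse = ", "), call. = FALSE)
  d <- d[, need]
  if (anyDuplicated(d$sample))
    stop("design file ", path, ": duplicated sample id", call. = FALSE)
  bad <- !d$condition %in% c("control", "untreated", "treated")
  if (any(bad))
    stop("design file ", path, ": unknown condition '",
         d$condition[which(bad)[1L]], "'", call. = FALSE)
  d
}

#' Write a sample-design table
#' @param design `data.frame` with columns `sample`, `condition`, `drug`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDesign <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene panel (one symbol per line, '#' comments)
#'
#' @param path Path to the panel file.
#' @return Character vector of gene symbols.
#' @export
readGenePanel <- function(path) {
  if (!file.exists(path))
    stop("gene panel file not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !grepl("^#", x)]
  unique(x)
}

#' Assemble a CdeiExperiment from a matrix and a design table
#'
#' @param exprs Numeric gene x sample matrix (nonnegative, finite).
#' @param design `data.frame` as returned by [readDesign()]. Samples present
#'   in the matrix but absent from the design are dropped with a message;
#'   design rows without a measured sample are an error.
#' @return A [CdeiExperiment-class].
#' @examples
#' m <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
#' d <- data.frame(sample = paste0("s", 1:4),
#'                 condition = c("control", "control", "untreated", "treated"),
#'                 drug = c("", "", "", "drugX"))
#' CdeiExperiment(m, d)
#' @export
CdeiExperiment <- function(exprs, design) {
  missing <- setdiff(design$sample, colnames(exprs))
  if (length(missing))
    stop("design samples not present in the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  extra <- setdiff(colnames(exprs), design$sample)
  if (length(extra))
    message("dropping ", length(extra),
            " sample(s) absent from the design: ",
            paste(extra, collapse = ", "))
  exprs <- exprs[, design$sample, drop = FALSE]
  cd <- S4Vectors::DataFrame(condition = design$condition,
                             drug = design$drug,
                             row.names = design$sample)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprs), colData = cd)
  new("CdeiExperiment", se)
}

#' Median-of-ratios normalization of raw counts
#'
#' Computes one size factor per sample as the median, over reference genes,
#' of the ratio of the sample's count to the gene's geometric mean across
#' samples; genes with a zero count in any sample are excluded from the
#' reference. Each column is divided by its size factor. This is the
#' standard RNA-seq median-of-ratios scheme and is delegated to
#' `DESeq2::estimateSizeFactorsForMatrix()`.
#'
#' @param counts Integer-valued gene x sample matrix of raw counts.
#' @return Normalized matrix with attribute `sizeFactors` (named numeric).
#' @examples
#' m <- matrix(c(2, 8, 4, 16), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' sf <- attr(normalizeCounts(m), "sizeFactors")  # ratio 1:2
#' @export
normalizeCounts <- function(counts) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("normalizeCounts expects nonnegative integer counts", call. = FALSE)
  if (!any(rowSums(counts == 0) == 0L))
    stop("no gene has positive counts in every sample; the median-of-ratios",
         " reference is empty. Supply pre-normalized expression instead.",
         call. = FALSE)
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  out <- sweep(counts, 2L, sf, "/")
  attr(out, "sizeFactors") <- sf
  message("size factors: ",
          paste(sprintf("%s=%.4g", names(sf), sf), collapse = ", "))
  out
}

#' Restrict an expression matrix to a gene panel
#'
#' Keeps the rows named in `panel`, in panel order; panel genes missing from
#' the matrix are counted and reported.
#'
#' @param exprs Gene x sample matrix.
#' @param panel Character vector of gene symbols.
#' @return Restricted matrix.
#' @export
restrictToPanel <- function(exprs, panel) {
  if (!length(panel))
    stop("gene panel is empty", call. = FALSE)
  panel <- unique(panel)
  keep <- panel[panel %in% rownames(exprs)]
  if (!length(keep))
    stop("no panel gene is present in the expression matrix", call. = FALSE)
  dropped <- length(panel) - length(keep)
  if (dropped > 0L)
    message(dropped, " panel gene(s) not measured; ", length(keep),
            " retained")
  exprs[keep, , drop = FALSE]
}

#' Per-sample signed log2 fold-change against the control pool
#'
#' For one case sample, deltaE(g) = log2((x_g + c) / (mean_control(x_g) + c))
#' with pseudocount `c`, where the denominator mean is the arithmetic mean of
#' the gene's expression over the control samples. Requested genes absent
#' from the measured matrix carry deltaE = 0, so unmeasured pathway members
#' propagate no perturbation.
#'
#' @param x A [CdeiExperiment-class].
#' @param sample A case (non-control) sample identifier.
#' @param genes Genes to report (e.g. one pathway's node set); defaults to
#'   all measured genes.
#' @param pseudocount Added to numerator and denominator; default 1.
#' @return Named numeric vector over `genes`.
#' @export
deltaE <- function(x, sample, genes = rownames(x), pseudocount = 1) {
  stopifnot(is(x, "CdeiExperiment"))
  if (!sample %in% colnames(x))
    stop("unknown sample: ", sample, call. = FALSE)
  cond <- as.character(SummarizedExperiment::colData(x)$condition)
  if (cond[match(sample, colnames(x))] == "control")
    stop("deltaE is defined for case samples; '", sample,
         "' is a control", call. = FALSE)
  full <- deltaEMatrix(x, pseudocount)
  out <- stats::setNames(numeric(length(genes)), genes)
  hit <- genes %in% rownames(full)
  out[hit] <- full[genes[hit], sample]
  out
}

# log2 fold-change of every case sample vs the control-pool mean, all
# measured genes at once.
deltaEMatrix <- function(x, pseudocount = 1) {
  m <- SummarizedExperiment::assay(x, "exprs")
  cond <- as.character(SummarizedExperiment::colData(x)$condition)
  ctrl <- m[, cond == "control", drop = FALSE]
  if (ncol(ctrl) < 2L)
    stop("need >= 2 control samples for the control pool", call. = FALSE)
  ref <- rowMeans(ctrl)
  case <- m[, cond != "control", drop = FALSE]
  log2(sweep(case + pseudocount, 1L, ref + pseudocount, "/"))
}
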