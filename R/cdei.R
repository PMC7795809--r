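#' Replicate sign-consistency weight of a pathway
#'
#' For a pathway whose mean SPIA score over the case samples is positive,
#' the weight is the fraction of case samples with a strictly positive
#' score; for a negative mean, the fraction with a strictly negative score.
#' Zero scores count toward neither branch, and a mean of exactly zero uses
#' the positive branch (a measure-zero tie, resolved deterministically).
#' The weight is 1 when every replicate agrees in sign with the mean and
#' shrinks toward 0 as replicates disagree.
#'
#' @param scores Numeric vector of per-case-sample SPIA scores for one
#'   pathway.
#' @return Weight in `[0, 1]`.
#' @examples
#' pathwayWeight(c(2, 1, -1))   # mean > 0 -> 2/3
#' pathwayWeight(c(-2, -1, 1))  # mean < 0 -> 2/3
#' @export
pathwayWeight <- function(scores) {
  if (!length(scores)) stop("no scores supplied", call. = FALSE)
  if (mean(scores) >= 0) sum(scores > 0) / length(scores)
  else                   sum(scores < 0) / length(scores)
}

#' Weighted mean SPIA score of a pathway
#'
#' The arithmetic mean of the case-sample scores multiplied by the
#' sign-consistency weight: SPIA_mu = mean(SPIA) * w_p.
#'
#' @inheritParams pathwayWeight
#' @return Scalar weighted mean.
#' @examples
#' spiaMu(c(2, 1, -1))  # (2/3) * (2/3) = 4/9
#' @export
spiaMu <- function(scores) {
  mean(scores) * pathwayWeight(scores)
}

#' One-sample t statistic of the per-pathway weighted means against zero
#'
#' Tests whether the vector of SPIA_mu values over the retained pathways
#' differs from 0; a dataset far from control yields a large |t|. Uses the
#' sample standard deviation (N - 1 denominator), df = N - 1, and a
#' two-sided p-value.
#'
#' @param mu Numeric vector of per-pathway SPIA_mu values (length >= 2,
#'   not constant).
#' @return List with `t`, `p`, `df`, `n`.
#' @export
oneSampleT <- function(mu) {
  if (length(mu) < 2L)
    stop("need >= 2 pathways for a t statistic", call. = FALSE)
  if (stats::sd(mu) == 0)
    stop("degenerate statistic: the SPIA_mu vector is constant",
         call. = FALSE)
  tt <- stats::t.test(mu, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), n = length(mu))
}

#' Drug efficiency index from two dataset t statistics
#'
#' CDEI = 2 * (|t_U| / (|t_T| + |t_U|) - 0.5), always in `[-1, 1]`:
#' 1 when the treated dataset is statistically indistinguishable from
#' control (|t_T| = 0, perfect restoration), 0 when treatment leaves the
#' perturbation unchanged (|t_T| = |t_U|), negative when treatment worsens
#' it (|t_T| > |t_U|). Defined as 0 when both statistics are 0 (no signal,
#' no claimed efficiency).
#'
#' @param tUntreated t statistic of the untreated dataset (absolute value
#'   taken internally).
#' @param tTreated t statistic of the treated dataset.
#' @return CDEI value in `[-1, 1]`.
#' @examples
#' cdeiScore(1.04, 0.67)  # 0.2164 -> prints as 0.22
#' cdeiScore(1.04, 2.06)  # -0.3290 -> prints as -0.33
#' @export
cdeiScore <- function(tUntreated, tTreated) {
  a <- abs(tUntreated)
  b <- abs(tTreated)
  ifelse(a + b == 0, 0, 2 * (a / (b + a) - 0.5))
}

#' Rank drugs by descending efficiency index
#'
#' Ties are broken lexicographically by drug label; ranks are 1..n.
#'
#' @param ranking `data.frame` with columns `drug` and `cdei` (e.g. the
#'   [cdeiRanking()] of a result, or any table with those columns).
#' @return The same `data.frame`, sorted, with a `rank` column.
#' @export
rankDrugs <- function(ranking) {
  if (!nrow(ranking)) stop("no drugs to rank", call. = FALSE)
  ord <- order(-ranking$cdei, ranking$drug)
  out <- ranking[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Summarize one case dataset into its t statistic
#'
#' Applies the weight and weighted mean per pathway over the dataset's case
#' samples, then the one-sample t test across pathways. The control
#' condition is never summarized: its SPIA_mu values are identically 0 by
#' construction.
#'
#' @param scores Pathway x case-sample score matrix from [scorePathways()].
#' @param samples Character vector naming the case samples of this dataset
#'   (all must be columns of `scores`).
#' @param label Dataset label for the output (e.g. `"untreated"` or a drug
#'   name).
#' @return List with `label`, `t`, `p`, `df`, `n`, `nProfiles` and
#'   `summary` (per-pathway `data.frame`: `pathway_id`, `mean_score`,
#'   `weight`, `spia_mu`).
#' @export
summarizeDataset <- function(scores, samples, label) {
  if (!all(samples %in% colnames(scores)))
    stop("score table is missing samples: ",
         paste(setdiff(samples, colnames(scores)), collapse = ", "),
         call. = FALSE)
  sub <- scores[, samples, drop = FALSE]
  w <- apply(sub, 1L, pathwayWeight)
  mu <- apply(sub, 1L, spiaMu)
  tt <- oneSampleT(mu)
  list(label = label, t = tt$t, p = tt$p, df = tt$df, n = tt$n,
       nProfiles = length(samples),
       summary = data.frame(pathway_id = rownames(scores),
                            mean_score = rowMeans(sub),
                            weight = w, spia_mu = mu,
                            row.names = NULL))
}

#' End-to-end drug efficiency analysis
#'
#' Runs the full pipeline on an expression experiment and a pathway
#' library: per-sample log2 fold-changes against the control pool, SPIA
#' perturbation scores per pathway and case sample, weighted per-pathway
#' means, one-sample t statistics for the untreated dataset and each drug,
#' and the efficiency index and ranking per drug.
#'
#' @param x A [CdeiExperiment-class] with >= 2 controls, >= 1 untreated
#'   sample and >= 1 treated sample.
#' @param pathways List of [Pathway-class] objects.
#' @param panel Optional gene panel (character vector); when given, the
#'   expression matrix is restricted to it before scoring.
#' @param pseudocount Pseudocount for the fold-changes; default 1.
#' @param tol Singularity threshold for the SPIA solve.
#' @return A [CdeiResult-class].
#' @examples
#' cfg <- simulationConfig(nPathways = 20, seed = 7,
#'                         restoration = c(good = 1, none = 0))
#' lib <- simulatePathways(cfg)
#' sim <- simulateDataset(cfg, lib)
#' res <- cdei(CdeiExperiment(sim$exprs, sim$design), lib)
#' cdeiRanking(res)
#' @export
cdei <- function(x, pathways, panel = NULL, pseudocount = 1, tol = 1e-10) {
  stopifnot(is(x, "CdeiExperiment"))
  if (!length(conditionSamples(x, "untreated")))
    stop("no untreated samples; the reference |t_U| cannot be computed",
         call. = FALSE)
  drugs <- drugLabels(x)
  if (!length(drugs))
    stop("no treated samples; nothing to rank", call. = FALSE)
  if (!is.null(panel)) {
    m <- restrictToPanel(SummarizedExperiment::assay(x, "exprs"), panel)
    cd <- SummarizedExperiment::colData(x)
    x <- CdeiExperiment(m, data.frame(sample = rownames(cd),
                                      condition = as.character(cd$condition),
                                      drug = as.character(cd$drug)))
  }
  sc <- scorePathways(x, pathways, pseudocount = pseudocount, tol = tol)

  u <- summarizeDataset(sc$scores, conditionSamples(x, "untreated"),
                        "untreated")
  ts <- list(u)
  for (d in drugs)
    ts <- c(ts, list(summarizeDataset(sc$scores, drugSamples(x, d), d)))

  nCtrl <- length(conditionSamples(x, "control"))
  tstats <- data.frame(
    dataset = c("control", vapply(ts, `[[`, "", "label")),
    sample_class = c("control", "untreated", rep("treated", length(drugs))),
    n_profiles = c(nCtrl, vapply(ts, function(z) z$nProfiles, 0L)),
    t_value = c(NA_real_, vapply(ts, `[[`, 0, "t")),
    p_value = c(NA_real_, vapply(ts, `[[`, 0, "p")),
    df = c(NA_integer_, vapply(ts, function(z) as.integer(z$df), 0L))
  )
  ranking <- data.frame(
    drug = drugs,
    abs_t_untreated = abs(u$t),
    abs_t_treated = abs(vapply(ts[-1L], `[[`, 0, "t")),
    cdei = vapply(ts[-1L], function(z) cdeiScore(u$t, z$t), 0)
  )
  ranking <- rankDrugs(ranking)
  summaries <- lapply(ts, `[[`, "summary")
  names(summaries) <- vapply(ts, `[[`, "", "label")
  new("CdeiResult", tstats = tstats, ranking = ranking,
      summaries = summaries, exclusions = sc$exclusions,
      nPathways = nrow(sc$scores))
}

# round half away from zero, the convention used for reported values
roundHalfAway <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Human-readable report table for a result
#'
#' One row per dataset with t, p and CDEI in reporting precision: t and
#' CDEI rounded half-away-from-zero to 2 decimals, p to 2 significant
#' figures; the control row carries blank statistics. Full precision stays
#' in [datasetTStats()] and [cdeiRanking()].
#'
#' @param result A [CdeiResult-class].
#' @return `data.frame` with columns `dataset`, `sample_class`,
#'   `n_profiles`, `t_value`, `p_value`, `cdei`.
#' @export
reportTable <- function(result) {
  stopifnot(is(result, "CdeiResult"))
  ts <- datasetTStats(result)
  rk <- cdeiRanking(result)
  cdeiCol <- rep(NA_real_, nrow(ts))
  cdeiCol[ts$sample_class == "untreated"] <- 0
  cdeiCol[match(rk$drug, ts$dataset)] <- rk$cdei
  data.frame(
    dataset = ts$dataset,
    sample_class = ts$sample_class,
    n_profiles = ts$n_profiles,
    t_value = ifelse(is.na(ts$t_value), "",
                     sprintf("%.2f", roundHalfAway(ts$t_value, 2L))),
    p_value = vapply(ts$p_value, function(p)
      if (is.na(p)) "" else format(signif(p, 2L), trim = TRUE), ""),
    cdei = ifelse(is.na(cdeiCol), "",
                  sprintf("%.2f", roundHalfAway(cdeiCol, 2L)))
  )
}

#' Write the report table as TSV
#'
#' @param result A [CdeiResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeCdeiReport <- function(result, path) {
  utils::write.table(reportTable(result), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run summary (key-value text)
#'
#' Records the pathway count, degrees of freedom, exclusions, full-precision
#' t statistics and the CDEI ranking — enough to audit every number in the
#' report.
#'
#' @param result A [CdeiResult-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRunSummary <- function(result, path) {
  ts <- datasetTStats(result)
  rk <- cdeiRanking(result)
  lines <- c(
    sprintf("n_pathways: %d", result@nPathways),
    sprintf("df: %d", result@nPathways - 1L),
    sprintf("excluded_pathways: %s",
            if (length(result@exclusions))
              paste(result@exclusions, collapse = ",") else "none")
  )
  for (i in seq_len(nrow(ts)))
    if (ts$sample_class[i] != "control")
      lines <- c(lines, sprintf("t[%s]: %.15g  p[%s]: %.15g",
                                ts$dataset[i], ts$t_value[i],
                                ts$dataset[i], ts$p_value[i]))
  for (i in seq_len(nrow(rk)))
    lines <- c(lines, sprintf("cdei[%s]: %.15g  rank: %d",
                              rk$drug[i], rk$cdei[i], rk$rank[i]))
  writeLines(lines, path)
  invisible(path)
}
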