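#' Configuration for the three-condition simulator
#'
#' Bundles and validates the parameters of the synthetic pathway library
#' and expression generator. Defaults describe the screening design the
#' package targets: a library of 241 pathways of ~10 genes, triplicate
#' control / untreated / treated samples, negative-binomial counts around a
#' mean of 100, and a 2 log2-unit perturbation applied to pathway root
#' genes in the untreated state.
#'
#' @param nPathways Number of pathways in the library.
#' @param genesPerPathway Genes per pathway.
#' @param edgeProbability Probability of a directed edge from a lower- to a
#'   higher-indexed gene (guarantees acyclicity).
#' @param inhibitionFraction Probability that an edge is inhibitory.
#' @param nControl,nUntreated,nTreated Replicates per condition (per drug
#'   for treated).
#' @param baselineMean Mean of the per-gene baseline expression (gene
#'   baselines are drawn log-normally around it).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param delta Perturbation effect in log2 units applied to pathway root
#'   genes in the untreated state (multiplier 2^delta).
#' @param restoration Named numeric vector: one simulated drug per entry,
#'   value rho in `[-1, 1]` = the fraction of the perturbation the drug
#'   removes. Treated means use multiplier 2^((1 - rho) * delta), so rho = 1
#'   restores the control mean structure, rho = 0 leaves the perturbation
#'   intact, and rho = -1 doubles it (an amplifying "anti-drug").
#' @param seed Integer seed; all randomness in [simulatePathways()] and
#'   [simulateDataset()] flows deterministically from it.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nPathways = 241L, genesPerPathway = 10L,
                             edgeProbability = 0.25,
                             inhibitionFraction = 0.25,
                             nControl = 3L, nUntreated = 3L, nTreated = 3L,
                             baselineMean = 100, dispersion = 0.1,
                             delta = 2,
                             restoration = c(full = 1, half = 0.5,
                                             none = 0),
                             seed = 1L) {
  stopifnot(
    nPathways >= 1L, genesPerPathway >= 1L,
    edgeProbability >= 0, edgeProbability <= 1,
    inhibitionFraction >= 0, inhibitionFraction <= 1,
    nControl >= 2L, nUntreated >= 1L, nTreated >= 1L,
    baselineMean > 0, dispersion >= 0, is.finite(delta),
    length(restoration) >= 1L, !is.null(names(restoration)),
    all(nzchar(names(restoration))),
    all(restoration >= -1 & restoration <= 1)
  )
  structure(
    list(nPathways = as.integer(nPathways),
         genesPerPathway = as.integer(genesPerPathway),
         edgeProbability = edgeProbability,
         inhibitionFraction = inhibitionFraction,
         nControl = as.integer(nControl),
         nUntreated = as.integer(nUntreated),
         nTreated = as.integer(nTreated),
         baselineMean = baselineMean, dispersion = dispersion,
         delta = delta, restoration = restoration,
         seed = as.integer(seed)),
    class = "SimulationConfig"
  )
}

#' Generate a random acyclic signed pathway library
#'
#' Each pathway draws its genes a fixed topological order; a directed edge
#' runs from gene i to gene j (i < j) with probability `edgeProbability`,
#' inhibitory with probability `inhibitionFraction`. Gene symbols are
#' pathway-local (`P001_G01`, ...), so the expression universe is the
#' disjoint union over pathways. Deterministic for a fixed seed.
#'
#' @param config A [simulationConfig()].
#' @return Named list of [Pathway-class] objects.
#' @export
simulatePathways <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  m <- config$genesPerPathway
  out <- vector("list", config$nPathways)
  for (k in seq_len(config$nPathways)) {
    pid <- sprintf("P%03d", k)
    genes <- sprintf("%s_G%02d", pid, seq_len(m))
    from <- character(); to <- character()
    if (m >= 2L) {
      idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
      pick <- stats::runif(nrow(idx)) < config$edgeProbability
      from <- genes[idx[pick, 1L]]
      to <- genes[idx[pick, 2L]]
    }
    sign <- if (length(from))
      ifelse(stats::runif(length(from)) < config$inhibitionFraction, -1, 1)
    else numeric()
    out[[k]] <- Pathway(pid, genes = genes,
                        edges = data.frame(from = from, to = to,
                                           sign = sign))
  }
  names(out) <- vapply(out, pathwayId, "")
  out
}

#' Generate a three-condition expression dataset with known ground truth
#'
#' Draws negative-binomial counts for control, untreated and per-drug
#' treated replicates. Untreated samples multiply the mean of every pathway
#' root gene by 2^delta; a drug with restoration fraction rho multiplies it
#' by 2^((1 - rho) * delta). The perturbation therefore enters at the
#' roots and reaches downstream genes only through the pathway topology at
#' scoring time. Deterministic for a fixed seed.
#'
#' @param config A [simulationConfig()].
#' @param library Pathway library from [simulatePathways()] (regenerated
#'   from `config` when missing).
#' @return List with `exprs` (gene x sample count matrix), `design`
#'   (sample/condition/drug `data.frame`), and `truth` (list: `delta`,
#'   `perturbedGenes`, `drugs` `data.frame` with `drug` and `rho`,
#'   `multipliers` gene x condition matrix of mean multipliers).
#' @export
simulateDataset <- function(config, library = simulatePathways(config)) {
  stopifnot(inherits(config, "SimulationConfig"))
  # distinct stream from the library draw, still a pure function of seed
  set.seed(config$seed + 777L)
  genes <- unlist(lapply(library, pathwayGenes), use.names = FALSE)
  if (anyDuplicated(genes)) genes <- unique(genes)
  roots <- unlist(lapply(library, rootGenes), use.names = FALSE)

  baseline <- stats::rlnorm(length(genes),
                            meanlog = log(config$baselineMean) - 0.125,
                            sdlog = 0.5)
  names(baseline) <- genes

  drugs <- names(config$restoration)
  conditions <- c("C", "U", drugs)
  mult <- matrix(1, length(genes), length(conditions),
                 dimnames = list(genes, conditions))
  mult[roots, "U"] <- 2^config$delta
  for (d in drugs)
    mult[roots, d] <- 2^((1 - config$restoration[[d]]) * config$delta)

  nrep <- c(config$nControl, config$nUntreated,
            rep(config$nTreated, length(drugs)))
  samples <- unlist(mapply(function(cn, n) sprintf("%s_%d", cn, seq_len(n)),
                           conditions, nrep, SIMPLIFY = FALSE))
  condOf <- rep(conditions, nrep)

  size <- if (config$dispersion > 0) 1 / config$dispersion else Inf
  exprs <- matrix(0, length(genes), length(samples),
                  dimnames = list(genes, samples))
  for (j in seq_along(samples)) {
    mu <- baseline * mult[, condOf[j]]
    exprs[, j] <- if (is.finite(size))
      stats::rnbinom(length(mu), mu = mu, size = size)
    else stats::rpois(length(mu), lambda = mu)
  }

  design <- data.frame(
    sample = samples,
    condition = ifelse(condOf == "C", "control",
                       ifelse(condOf == "U", "untreated", "treated")),
    drug = ifelse(condOf %in% c("C", "U"), "", condOf)
  )
  truth <- list(delta = config$delta, perturbedGenes = roots,
                drugs = data.frame(drug = drugs,
                                   rho = unname(config$restoration)),
                multipliers = mult)
  list(exprs = exprs, design = design, truth = truth)
}

#' Write a ground-truth record as TSV
#'
#' One row per simulated drug (`drug`, `rho`) preceded by comment lines
#' recording delta and the perturbed genes.
#'
#' @param truth The `truth` element of [simulateDataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# delta: %g", truth$delta),
               sprintf("# perturbed_genes: %s",
                       paste(truth$perturbedGenes, collapse = ",")),
               "drug\trho"), con)
  writeLines(sprintf("%s\t%g", truth$drugs$drug, truth$drugs$rho), con)
  invisible(path)
}
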