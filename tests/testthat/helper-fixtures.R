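# Shared fixtures: all built in code at test time.

# Random acyclic signed pathway: edges only run from lower to higher index.
makeRandomDag <- function(n = 6L, edgeProb = 0.4, inhibProb = 0.5,
                          id = "Pr") {
  genes <- paste0("g", seq_len(n))
  from <- character(); to <- character()
  if (n >= 2L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pick <- runif(nrow(idx)) < edgeProb
    from <- genes[idx[pick, 1L]]
    to <- genes[idx[pick, 2L]]
  }
  sgn <- if (length(from)) ifelse(runif(length(from)) < inhibProb, -1, 1)
         else numeric()
  Pathway(id, genes = genes,
          edges = data.frame(from = from, to = to, sign = sgn))
}

randomDelta <- function(pathway) {
  setNames(rnorm(nGenes(pathway)), pathwayGenes(pathway))
}

writeTempPathways <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("pathway_id\tsource\ttarget\tinteraction", lines), f)
  f
}

# Tiny three-condition experiment with explicit values.
toyExperiment <- function() {
  m <- matrix(c(4, 4, 3, 3, 7, 10,
                2, 2, 2, 2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"),
                              c("c1", "c2", "u1", "u2", "t1", "t2")))
  d <- data.frame(
    sample = colnames(m),
    condition = c("control", "control", "untreated", "untreated",
                  "treated", "treated"),
    drug = c("", "", "", "", "dx", "dx"))
  CdeiExperiment(m, d)
}
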