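test_that("edge-list parsing transcribes pathways faithfully", {
  f <- writeTempPathways(c("P1\tA\tB\tactivation", "P1\tA\tC\tinhibition"))
  ps <- readPathways(f)
  expect_length(ps, 1L)
  p <- ps[["P1"]]
  expect_equal(pathwayGenes(p), c("A", "B", "C"))
  expect_equal(pathwayEdges(p)$sign, c(1, -1))

  # empty file (header only, and truly empty) -> empty list, not an error
  expect_length(readPathways(writeTempPathways(character())), 0L)
  empty <- tempfile(); file.create(empty)
  expect_length(readPathways(empty), 0L)

  # multi-pathway files are split; a gene may live in several pathways
  f2 <- writeTempPathways(c("P1\tA\tB\tactivation", "P2\tA\tB\tinhibition"))
  ps2 <- readPathways(f2)
  expect_named(ps2, c("P1", "P2"))
  expect_equal(pathwayEdges(ps2$P2)$sign, -1)
})

test_that("malformed edge lists fail with located errors", {
  f <- writeTempPathways(c("P1\tA\tB\tactivation", "P1\tA\tB\tinhibition"))
  expect_error(readPathways(f), "conflicting signs")
  f <- writeTempPathways(c("P1\tA\tB\tactivation", "P1\tA\tB\tactivation"))
  expect_error(readPathways(f), "duplicate edge")
  f <- writeTempPathways("P1\tA\tB\tbinds")
  expect_error(readPathways(f), "line 2.*binds")
  f <- writeTempPathways("P1\tA\tB")
  expect_error(readPathways(f), "4 tab-separated fields")
})

test_that("load -> write -> load round-trips to identical pathways", {
  set.seed(11)
  ps <- lapply(1:4, function(k)
    makeRandomDag(sample(2:8, 1), id = paste0("P", k)))
  names(ps) <- vapply(ps, pathwayId, "")
  f <- tempfile(fileext = ".tsv")
  writePathways(ps, f)
  back <- readPathways(f)
  # pathways with no edges are not representable in an edge list
  hasEdges <- vapply(ps, function(p) nrow(pathwayEdges(p)) > 0, NA)
  expect_identical(names(back), names(ps)[hasEdges])
  for (nm in names(back)) {
    expect_identical(pathwayGenes(back[[nm]]),
                     unique(c(rbind(pathwayEdges(ps[[nm]])$from,
                                    pathwayEdges(ps[[nm]])$to))))
    expect_identical(pathwayEdges(back[[nm]]), pathwayEdges(ps[[nm]]))
  }
})

test_that("Pathway validity enforces the graph invariants", {
  expect_error(Pathway("P", genes = c("A", "A")), "unique")
  expect_error(Pathway("P", genes = "A",
                       edges = data.frame(from = "A", to = "Z", sign = 1)),
               "endpoint")
  expect_error(Pathway("P", genes = c("A", "B"),
                       edges = data.frame(from = "A", to = "B", sign = 2)),
               "sign")
  # n >= 1, edges may be empty
  expect_s4_class(Pathway("P", genes = "A"), "Pathway")
})

test_that("the B matrix follows the out-degree-normalized sign rule", {
  fan <- Pathway("fan", edges = data.frame(
    from = "A", to = c("B", "C"), sign = c(1, -1)))
  B <- betaEntries(betaMatrix(fan))
  expect_equal(B["B", "A"], 0.5)
  expect_equal(B["C", "A"], -0.5)
  expect_equal(sum(B != 0), 2L)
  expect_equal(unname(nDown(betaMatrix(fan))), c(2L, 0L, 0L))

  chain <- Pathway("chain", edges = data.frame(
    from = c("A", "B"), to = c("B", "C"), sign = c(1, 1)))
  Bc <- betaEntries(betaMatrix(chain))
  expect_equal(Bc["B", "A"], 1)
  expect_equal(Bc["C", "B"], 1)
  expect_equal(sum(Bc != 0), 2L)

  bare <- Pathway("bare", genes = c("A", "B", "C"))
  expect_equal(betaEntries(betaMatrix(bare)),
               matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                               c("A", "B", "C"))))
})

test_that("columns of B sum to 1 in absolute value iff the gene regulates", {
  set.seed(42)
  for (rep in 1:20) {
    p <- makeRandomDag(sample(2:10, 1))
    bm <- betaMatrix(p)
    colAbs <- colSums(abs(betaEntries(bm)))
    expect_equal(unname(colAbs[nDown(bm) > 0]),
                 rep(1, sum(nDown(bm) > 0)))
    expect_equal(unname(colAbs[nDown(bm) == 0]),
                 rep(0, sum(nDown(bm) == 0)))
    expect_equal(unname(diag(betaEntries(bm))), rep(0, nGenes(p)))
  }
})

test_that("pathway diagnostics flag cycles, singularity and isolation", {
  chain <- Pathway("chain", edges = data.frame(
    from = c("A", "B"), to = c("B", "C"), sign = c(1, 1)))
  d <- validatePathway(chain)
  expect_true(d$invertible)
  expect_true(d$acyclic)
  expect_length(d$isolated, 0L)

  cyc <- Pathway("cyc", edges = data.frame(
    from = c("A", "B"), to = c("B", "A"), sign = c(1, 1)))
  d <- validatePathway(cyc)  # B has eigenvalue 1 -> (I - B) singular
  expect_false(d$invertible)
  expect_false(d$acyclic)

  lone <- Pathway("lone", genes = "A")
  d <- validatePathway(lone)
  expect_true(d$invertible)
  expect_true(d$acyclic)
  expect_identical(d$isolated, "A")
})

test_that("acyclic pathways always yield an invertible (I - B)", {
  set.seed(7)
  for (rep in 1:25) {
    p <- makeRandomDag(sample(2:12, 1), edgeProb = 0.6)
    d <- validatePathway(p)
    expect_true(d$acyclic)
    expect_true(d$invertible)
  }
})

test_that("root genes are regulators without upstream regulators", {
  fan <- Pathway("fan", edges = data.frame(
    from = c("A", "A", "B"), to = c("B", "C", "C"), sign = 1))
  expect_identical(rootGenes(fan), "A")
  expect_identical(rootGenes(Pathway("bare", genes = "X")), character())
})
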