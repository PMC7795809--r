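test_that("the sign-consistency weight follows the mean's branch", {
  expect_equal(pathwayWeight(c(2, 1, -1)), 2 / 3)   # positive branch
  expect_equal(pathwayWeight(c(-2, -1, 1)), 2 / 3)  # negative branch
  expect_equal(pathwayWeight(c(1, 2, 3)), 1)
  # zeros count toward neither numerator
  expect_equal(pathwayWeight(c(2, 0, 0, 1)), 1 / 2)
  # mean exactly zero -> positive branch, deterministically
  expect_equal(pathwayWeight(c(1, -1)), 1 / 2)
  expect_equal(pathwayWeight(c(0, 0)), 0)
  expect_error(pathwayWeight(numeric()), "no scores")
})

test_that("the weighted mean multiplies the mean by the weight", {
  expect_equal(spiaMu(c(2, 1, -1)), (2 / 3) * (2 / 3))
  expect_equal(spiaMu(c(0, 0, 0)), 0)
  expect_equal(spiaMu(3.7), 3.7)  # single positive score: w = 1
  expect_equal(spiaMu(c(-4, -2)), -3)
})

test_that("the dataset statistic is a one-sample t with N - 1 df", {
  set.seed(21)
  mu <- rnorm(15, mean = 0.4)
  tt <- oneSampleT(mu)
  expect_equal(tt$t, mean(mu) / (sd(mu) / sqrt(15)))
  expect_equal(tt$df, 14)
  expect_equal(tt$p, 2 * pt(-abs(tt$t), 14))
  # mean exactly zero -> t = 0, p = 1
  sym <- c(-2, -1, 1, 2)
  expect_equal(oneSampleT(sym)$t, 0)
  expect_equal(oneSampleT(sym)$p, 1)
  expect_error(oneSampleT(rep(1, 5)), "constant")
  expect_error(oneSampleT(3), ">= 2 pathways")
})

test_that("the efficiency index matches its defining formula and bounds", {
  # screen rows reproduced at full precision before rounding
  expect_equal(cdeiScore(1.04, 0.67), 2 * (1.04 / 1.71 - 0.5))
  expect_equal(round(cdeiScore(1.04, 0.67), 2), 0.22)
  expect_equal(round(cdeiScore(1.04, 2.06), 2), -0.33)
  # sign of the inputs is irrelevant
  expect_equal(cdeiScore(-2.78, -0.03), cdeiScore(2.78, 0.03))
  # boundary identities
  expect_identical(cdeiScore(1.3, 1.3), 0)
  expect_identical(cdeiScore(1.3, 0), 1)
  expect_identical(cdeiScore(0, 1.3), -1)
  expect_identical(cdeiScore(0, 0), 0)
})

test_that("drugs rank by descending index with lexicographic ties", {
  rk <- rankDrugs(data.frame(drug = c("b", "a", "c"),
                             cdei = c(0.5, 0.5, 0.9)))
  expect_identical(rk$drug, c("c", "a", "b"))
  expect_identical(rk$rank, 1:3)
  single <- rankDrugs(data.frame(drug = "only", cdei = 0.1))
  expect_identical(single$rank, 1L)
  expect_error(rankDrugs(data.frame(drug = character(),
                                    cdei = numeric())), "no drugs")
})

test_that("dataset summaries compose weight, mean and t correctly", {
  # two pathways whose weighted means are +a and -a -> t = 0
  scores <- rbind(p1 = c(2, 2, 2), p2 = c(-2, -2, -2))
  colnames(scores) <- c("s1", "s2", "s3")
  s <- summarizeDataset(scores, c("s1", "s2", "s3"), "u")
  expect_equal(s$summary$spia_mu, c(2, -2))
  expect_equal(s$t, 0)
  expect_equal(s$df, 1)
  # all-zero scores -> constant weighted means -> degenerate statistic
  zero <- rbind(p1 = c(0, 0), p2 = c(0, 0))
  colnames(zero) <- c("s1", "s2")
  expect_error(summarizeDataset(zero, c("s1", "s2"), "u"), "constant")
  # missing sample -> error naming it
  expect_error(summarizeDataset(scores, c("s1", "s9"), "u"), "s9")
})

test_that("a known positive per-pathway shift yields a positive t", {
  set.seed(31)
  cfg <- simulationConfig(nPathways = 25, genesPerPathway = 8,
                          restoration = c(dx = 0), seed = 31)
  lib <- simulatePathways(cfg)
  sim <- simulateDataset(cfg, lib)
  x <- CdeiExperiment(sim$exprs, sim$design)
  sc <- suppressMessages(scorePathways(x, lib))
  u <- summarizeDataset(sc$scores,
                        sim$design$sample[sim$design$condition ==
                                            "untreated"], "untreated")
  expect_gt(u$t, 2)  # upregulated roots push pathway scores up on average
})

test_that("the end-to-end result carries consistent tables", {
  cfg <- simulationConfig(nPathways = 15, genesPerPathway = 6,
                          restoration = c(good = 1, bad = 0), seed = 8)
  lib <- simulatePathways(cfg)
  sim <- simulateDataset(cfg, lib)
  res <- suppressMessages(cdei(CdeiExperiment(sim$exprs, sim$design), lib))
  ts <- datasetTStats(res)
  expect_identical(ts$sample_class, c("control", "untreated", "treated",
                                      "treated"))
  expect_true(all(is.na(ts$t_value[1])))
  rk <- cdeiRanking(res)
  expect_setequal(rk$drug, c("good", "bad"))
  expect_true(all(rk$cdei >= -1 & rk$cdei <= 1))
  expect_equal(rk$abs_t_untreated,
               rep(abs(ts$t_value[ts$dataset == "untreated"]), 2))
  # cdei recomputes from the t columns of the same result
  expect_equal(rk$cdei,
               cdeiScore(rk$abs_t_untreated, rk$abs_t_treated))
  # report table: one row per dataset, control statistics blank
  rep_ <- reportTable(res)
  expect_identical(rep_$t_value[1], "")
  expect_equal(nrow(rep_), 4L)
  # df consistent with retained pathway count
  expect_equal(unique(ts$df[-1]), res@nPathways - 1L)
})

test_that("reported values round half away from zero", {
  r <- new("CdeiResult",
           tstats = data.frame(dataset = c("control", "untreated", "dx"),
                               sample_class = c("control", "untreated",
                                                "treated"),
                               n_profiles = c(3L, 3L, 3L),
                               t_value = c(NA, 2.345, -2.345),
                               p_value = c(NA, 0.0199, 0.0199),
                               df = c(NA, 240L, 240L)),
           ranking = data.frame(drug = "dx", abs_t_untreated = 2.345,
                                abs_t_treated = 2.345, cdei = 0.125,
                                rank = 1L),
           summaries = list(), exclusions = character(),
           nPathways = 241L)
  tab <- reportTable(r)
  expect_identical(tab$t_value[2:3], c("2.35", "-2.35"))
  expect_identical(tab$cdei[3], "0.13")
  expect_identical(tab$p_value[2], "0.02")
})
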