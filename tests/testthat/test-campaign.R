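test_that("pool expansion adds only one-mutation extensions of hits", {
  # 5-position toy landscape: all singles of "ACDEF" at position 1-2 plus
  # assorted doubles
  singles <- c("A1G", "A1V", "C2G", "C2W")
  doubles <- c("A1G:C2G", "A1G:D3W", "A1V:C2G", "C2G:D3W", "D3W:E4Y")
  acts <- c(1, -1, 0.5, -0.2, 2, 1.5, 0.1, 0.3, 0.9)
  ls1 <- Landscape("ACDEF", c(singles, doubles), acts)
  acc <- records(ls1)$id

  # round-1 measured: one hit (A1G, activity 1 > 0), one miss (A1V)
  measured <- c(A1G = 1, A1V = -1)
  pool <- expandPool(measured, ls1, acc)
  # all unmeasured singles plus doubles containing the hit A1G
  expect_setequal(pool, c("C2G", "C2W", "A1G:C2G", "A1G:D3W"))

  # no hits above wild type -> singles only
  pool2 <- expandPool(c(A1G = -5, A1V = -1), ls1, acc)
  expect_setequal(pool2, c("C2G", "C2W"))

  # a measured double hit unlocks nothing here (no triples exist)
  pool3 <- expandPool(c(`A1G:C2G` = 2), ls1, acc)
  expect_setequal(pool3, c("A1G", "A1V", "C2G", "C2W"))
  expect_error(expandPool(numeric(0), ls1, acc), "measured")
})

test_that("metrics count selections at the accessible percentile thresholds", {
  # 200 accessible mutants with activities 1..200
  ids <- paste0("A", 1:200, "C")
  ls1 <- Landscape(paste(rep("A", 200), collapse = ""), ids, 1:200)
  acc <- records(ls1)$id
  # 5 of the top 20 selected
  sel <- list(ids[c(181, 185, 190, 195, 200, 10, 20, 30)])
  m <- computeMetrics(sel, ls1, acc)
  expect_equal(m@cumulativeTop10Hits, 5L)
  expect_true(m@foundTop1)  # id 200 is the single best
  # without the best two, no top-1% pick (99th percentile ~ 199.01)
  m2 <- computeMetrics(list(ids[c(181, 198)]), ls1, acc)
  expect_false(m2@foundTop1)
  # selecting everything: ceil(0.1 * N) hits and a guaranteed top-1%
  m3 <- computeMetrics(list(ids), ls1, acc)
  expect_equal(m3@cumulativeTop10Hits, 20L)
  expect_true(m3@foundTop1)
})

test_that("zero-shot campaigns walk down the naturalness ranking", {
  orc <- benchmarkOracle(L = 25, dim = 16)
  ls1 <- generateLandscape(orc)
  cfg <- campaignConfig(strategy = "zero_shot", seed = 4,
                        trainCfg = testTrainConfig(dim = 16L))
  res <- suppressMessages(runCampaign(ls1, orc, cfg))
  acc <- accessibleIds(res$split)
  e <- naturalnessEntries(naturalnessTable(logProbMatrix(orc)))
  eAcc <- e[e$id %in% acc, ]
  expected <- eAcc$id[order(-eAcc$naturalness)][1:48]
  got <- unlist(lapply(res$rounds, function(r) selectedIds(r@selected)))
  expect_identical(got, expected)
  # selections never leave the accessible half and are never repeated
  expect_true(all(got %in% acc))
  expect_equal(anyDuplicated(got), 0L)
})

test_that("random campaigns measure distinct accessible mutants, reproducibly", {
  orc <- benchmarkOracle(L = 20, dim = 16)
  ls1 <- generateLandscape(orc)
  cfg <- campaignConfig(strategy = "random", seed = 11,
                        trainCfg = testTrainConfig(dim = 16L))
  r1 <- suppressMessages(runCampaign(ls1, orc, cfg))
  r2 <- suppressMessages(runCampaign(ls1, orc, cfg))
  ids1 <- unlist(lapply(r1$rounds, function(r) selectedIds(r@selected)))
  expect_equal(length(unique(ids1)), 48L)
  expect_identical(ids1,
                   unlist(lapply(r2$rounds,
                                 function(r) selectedIds(r@selected))))
  expect_identical(r1$metrics@perRoundHits, r2$metrics@perRoundHits)
})

test_that("the random-forest baseline trains on measurements from round 2", {
  orc <- cleanOracle(L = 15, dim = 16)
  ls1 <- generateLandscape(orc)
  cfg <- campaignConfig(strategy = "random_forest", rounds = 2, seed = 2,
                        trainCfg = testTrainConfig(dim = 16L),
                        heldoutDiagnosticMax = 100L)
  res <- suppressMessages(runCampaign(ls1, orc, cfg))
  expect_true(is.na(res$rounds[[1]]@heldoutSpearman))
  expect_false(is.na(res$rounds[[2]]@heldoutSpearman))
  expect_equal(length(selectedIds(res$rounds[[2]]@selected)), 16L)
})

test_that("bootstrap replicates are paired and reproducible", {
  orc <- benchmarkOracle(L = 20, dim = 16)
  ls1 <- generateLandscape(orc)
  configs <- list(
    zero_shot = campaignConfig(strategy = "zero_shot",
                               trainCfg = testTrainConfig(dim = 16L)),
    random = campaignConfig(strategy = "random",
                            trainCfg = testTrainConfig(dim = 16L)))
  b1 <- suppressMessages(
    bootstrapBenchmark(ls1, orc, configs, nReplicates = 3, seed = 5))
  b2 <- suppressMessages(
    bootstrapBenchmark(ls1, orc, configs, nReplicates = 3, seed = 5))
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 6L)
  expect_true(all(table(b1$replicate) == 2L))
})

test_that("the paired Wilcoxon on log counts matches exact enumeration", {
  # six all-positive log-ratios: exact one-sided p = 1 / 2^6
  res <- wilcoxonLogRatio(c(4, 5, 6, 7, 8, 9), c(3, 4, 5, 6, 7, 8))
  expect_equal(res$p, 1 / 64)
  expect_false(res$degenerate)

  # identical counts: degenerate, p = 1
  resEq <- wilcoxonLogRatio(c(3, 3, 3), c(3, 3, 3))
  expect_true(resEq$degenerate)
  expect_equal(resEq$p, 1)

  # zeros trigger the +1 shift
  expect_message(res0 <- wilcoxonLogRatio(c(0, 5, 6), c(1, 3, 2)), "shift")
  expect_true(res0$shifted)

  # n above the exact range still yields a one-sided p in (0, 1)
  a <- 2:31; b <- rev(2:31)
  pBig <- wilcoxonLogRatio(a, b)$p
  expect_true(pBig > 0 && pBig < 1)
})
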