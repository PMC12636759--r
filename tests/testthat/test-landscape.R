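test_that("DMS CSV round-trips into a Landscape, skipping NaN scores", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mutant,DMS_score", "A1G,0.1", "A1V,0.2", "C2G,0.3"), path)
  ls1 <- suppressMessages(readDmsCsv(path, wildType = "AC"))
  expect_s4_class(ls1, "Landscape")
  expect_equal(nrow(records(ls1)), 3L)
  expect_equal(unname(activities(ls1, "A1V")), 0.2)

  # a NaN row is skipped with a warning, leaving 3 of 4 rows
  writeLines(c("mutant,DMS_score", "A1G,0.1", "A1V,NaN", "C2G,0.3",
               "C2W,-0.5"), path)
  expect_warning(ls2 <- suppressMessages(readDmsCsv(path, wildType = "AC")),
                 "1 row")
  expect_equal(nrow(records(ls2)), 3L)

  writeLines("mutant,DMS_score", path)
  expect_error(suppressMessages(readDmsCsv(path)), "empty")
})

test_that("wild type resolution: FASTA sidecar beats reconstruction, gaps error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mutant,DMS_score", "A1G,0.1", "C2G,0.3"), path)
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">wt", "AC"), fa)
  expect_identical(wildType(suppressMessages(readDmsCsv(path, fasta = fa))),
                   "AC")
  # reconstruction works when every position is mutated somewhere
  expect_identical(wildType(suppressMessages(readDmsCsv(path))), "AC")
  # position 2 never mutated -> unknown letter
  writeLines(c("mutant,DMS_score", "A1G,0.1", "C3G,0.3"), path)
  expect_error(suppressMessages(readDmsCsv(path)), "position")
  # contradictory wild-type letters at one position
  writeLines(c("mutant,DMS_score", "A1G,0.1", "C1G,0.3"), path)
  expect_error(suppressMessages(readDmsCsv(path)), "inconsistent")
})

test_that("landscape validity rejects mismatched or out-of-range mutations", {
  expect_error(Landscape("AC", "G1A", 0.5), "disagrees")
  expect_error(Landscape("AC", "A5G", 0.5), "beyond")
  expect_error(Landscape("AC", c("A1G", "A1G"), c(1, 2)), "unique")
})

test_that("holdout split partitions deterministically at round(fraction*N)", {
  orc <- cleanOracle(L = 10, dim = 8)
  ls1 <- generateLandscape(orc)
  sp <- holdoutSplit(ls1, 0.5, seed = 7)
  ids <- records(ls1)$id
  expect_equal(length(heldOutIds(sp)), round(0.5 * length(ids)))
  expect_setequal(c(accessibleIds(sp), heldOutIds(sp)), ids)
  expect_length(intersect(accessibleIds(sp), heldOutIds(sp)), 0L)
  # deterministic given seed; different seeds differ
  sp2 <- holdoutSplit(ls1, 0.5, seed = 7)
  expect_identical(heldOutIds(sp), heldOutIds(sp2))
  sp3 <- holdoutSplit(ls1, 0.5, seed = 8)
  expect_false(setequal(heldOutIds(sp), heldOutIds(sp3)))
  expect_error(holdoutSplit(ls1, 1.2, seed = 1), "fraction")
})

test_that("difficulty is the min-max-scaled 99.375th percentile", {
  # 161 sorted values: the percentile lands exactly on the 160th order
  # statistic (1 + 0.99375 * 160 = 160), set to 4 with range [0, 10]
  a <- c(seq(0, 3.9, length.out = 159), 4, 10)
  ls1 <- Landscape(paste(rep("A", 161), collapse = ""),
                   paste0("A", seq_along(a), "C"), a)
  expect_equal(difficulty(ls1), 0.4)

  # all upper mass at the maximum -> difficulty 1
  b <- c(0, rep(10, 300))
  ls2 <- Landscape(paste(rep("A", 301), collapse = ""),
                   paste0("A", seq_along(b), "C"), b)
  expect_equal(difficulty(ls2), 1.0)

  # uniform activities: empirical percentile ~ 0.99375
  u <- withr::with_seed(1, stats::runif(10000))
  ls3 <- Landscape(paste(rep("A", 10000), collapse = ""),
                   paste0("A", seq_along(u), "C"), u)
  expect_equal(difficulty(ls3), 0.99375, tolerance = 0.005)

  expect_error(difficulty(Landscape("AC", c("A1G", "C2G"), c(1, 1))),
               "zero range")
})

test_that("difficulty is invariant to affine rescaling of activities", {
  orc <- cleanOracle(L = 12, dim = 8)
  ls1 <- generateLandscape(orc)
  d0 <- difficulty(ls1)
  rec <- records(ls1)
  ls2 <- Landscape(wildType(ls1), rec$mutant, 3.7 * rec$activity - 11)
  expect_equal(difficulty(ls2), d0, tolerance = 1e-12)
})
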