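test_that("naturalness is the summed log-likelihood ratio over mutated sites", {
  # construct exact log-probabilities at position 1: wt A at log -0.5,
  # mutant C at log -1.0, remaining mass spread over the other letters
  rest <- (1 - exp(-0.5) - exp(-1)) / 18
  v <- matrix(log(rest), 2, 20, dimnames = list(NULL, AA_ALPHABET))
  v[1, "A"] <- -0.5; v[1, "C"] <- -1.0
  v[2, "C"] <- log(1 - 19 * rest)
  lp <- methods::new("LogProbMatrix", values = v, wildType = "AC")

  expect_equal(naturalnessScore(NULL, lp), 0)
  expect_equal(naturalnessScore("A1C", lp), -0.5)
  expect_error(naturalnessScore("A5C", lp), "range")
  expect_error(naturalnessScore("C1A", lp), "disagrees")
})

test_that("a multi-mutant scores the sum of its single-mutant scores", {
  lp <- randomLogProbs("ACDEFGHIKL", seed = 4)
  s12 <- naturalnessScore("A1W:D3Y", lp)
  expect_equal(s12, naturalnessScore("A1W", lp) + naturalnessScore("D3Y", lp),
               tolerance = 1e-12)
})

test_that("the table has L x 19 entries matching per-mutation scoring", {
  lp <- randomLogProbs("ACDEFGHIKL", seed = 2)
  tab <- naturalnessTable(lp)
  e <- naturalnessEntries(tab)
  expect_equal(nrow(e), 10L * 19L)
  wtChars <- strsplit("ACDEFGHIKL", "")[[1]]
  expect_false(any(e$mutAa == wtChars[e$position]))
  idx <- withr::with_seed(1, sample(nrow(e), 25))
  for (i in idx)
    expect_equal(e$naturalness[i], naturalnessScore(e$id[i], lp),
                 tolerance = 1e-12)
})

test_that("naturalness ignores per-position shifts of the log-probabilities", {
  lp <- randomLogProbs("ACDEF", seed = 6)
  # shifting a row's logits by a constant renormalises to the same
  # distribution, so the table must be unchanged
  shifted <- exp(lp@values + c(1, -2, 0.5, 0, 3))
  shifted <- log(shifted / rowSums(shifted))
  dimnames(shifted) <- dimnames(lp@values)
  lp2 <- methods::new("LogProbMatrix", values = shifted, wildType = "ACDEF")
  expect_equal(naturalnessEntries(naturalnessTable(lp2))$naturalness,
               naturalnessEntries(naturalnessTable(lp))$naturalness,
               tolerance = 1e-9)
})

test_that("uncapped zero-shot selection equals a full sort", {
  lp <- randomLogProbs("ACDEFGHIKLMNPQRSTVWY", seed = 3)
  tab <- naturalnessTable(lp)
  b <- zeroShotSelect(tab, 16)
  e <- naturalnessEntries(tab)
  topIds <- e$id[order(-e$naturalness)][1:16]
  expect_identical(selectedIds(b), topIds)
  expect_equal(selectionTrace(b), sort(e$naturalness, decreasing = TRUE)[1:16])
})

test_that("the per-locus cap skips a locus once it holds that many picks", {
  # 6 candidates at locus 1 carry the 6 best scores; cap 3, batch 4
  # -> three locus-1 picks plus the best other-locus candidate
  e <- data.frame(
    id = c(paste0("A1", c("C", "D", "E", "F", "G", "H")), "C2A", "C2D"),
    position = c(rep(1L, 6), 2L, 2L),
    mutAa = c("C", "D", "E", "F", "G", "H", "A", "D"),
    naturalness = c(10, 9, 8, 7, 6, 5, 4, 3))
  tab <- methods::new("NaturalnessTable", entries = e, wildType = "AC")
  b <- zeroShotSelect(tab, 4, maxPerLocus = 3)
  expect_identical(selectedIds(b), c("A1C", "A1D", "A1E", "C2A"))
  expect_error(zeroShotSelect(tab, 6, maxPerLocus = 3), "insufficient")
})

test_that("excluded ids are never selected, making successive batches disjoint", {
  lp <- randomLogProbs("ACDEFGHIKLMNPQRSTVWY", seed = 8)
  tab <- naturalnessTable(lp)
  b1 <- zeroShotSelect(tab, 16)
  b2 <- zeroShotSelect(tab, 16, exclude = selectedIds(b1))
  b3 <- zeroShotSelect(tab, 16, exclude = c(selectedIds(b1),
                                            selectedIds(b2)))
  all3 <- c(selectedIds(b1), selectedIds(b2), selectedIds(b3))
  expect_equal(length(unique(all3)), 48L)
  # batches 1-3 are naturalness ranks 1-16, 17-32, 33-48
  e <- naturalnessEntries(tab)
  expect_identical(all3, e$id[order(-e$naturalness)][1:48])
})
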