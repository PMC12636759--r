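test_that("top-N selection is a consensus sort with stable ties", {
  pred <- ensembleFromScores(rbind(c(3, 1, 2), c(3, 1, 2)) + 0.0,
                             ids = c("x", "y", "z"))
  b <- topNSelect(pred, 2)
  expect_identical(selectedIds(b), c("x", "z"))
  expect_identical(selectedIds(topNSelect(pred, 10)), c("x", "z", "y"))
})

test_that("the covariance posterior matches Gaussian conditioning", {
  # identity: no coupling, conditioning removes a coordinate
  expect_equal(covariancePosterior(diag(3), 2), diag(2))
  # perfect correlation collapses to zero
  S2 <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(covariancePosterior(S2, 1), matrix(0, 1, 1))
  # random PSD vs the independent block-inverse oracle
  for (s in 1:10) {
    Sig <- randomPsd(6, seed = s)
    y <- withr::with_seed(100 + s, rnorm(6))
    i <- (s %% 6) + 1
    orc <- conditionOracle(y, Sig, i, yObs = min(y))
    expect_equal(covariancePosterior(Sig, i), orc$cov, tolerance = 1e-10)
    expect_equal(meanPosterior(y, Sig, i, min(y)), orc$mean,
                 tolerance = 1e-10)
  }
  expect_error(covariancePosterior(matrix(c(0, 0, 0, 1), 2), 1), "positive")
})

test_that("the mean posterior responds to the lie only through coupling", {
  Sig <- randomPsd(5, seed = 3)
  y <- withr::with_seed(9, rnorm(5))
  # lie equal to the prediction: no update
  expect_equal(meanPosterior(y, Sig, 2, y[2]), y[-2])
  # zero coupling: unchanged regardless of the lie
  SigD <- diag(diag(Sig))
  expect_equal(meanPosterior(y, SigD, 2, -100), y[-2])
})

test_that("a pessimistic lie demotes the correlated runner-up", {
  # unit variances, candidates 1 and 2 perfectly correlated, 3 independent
  Sig <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  y <- c(1.0, 0.9, 0.0)
  y2 <- meanPosterior(y, Sig, 1, 0.0)  # lie = pool minimum
  expect_equal(unname(y2), c(-0.1, 0.0))
  expect_gt(y2[2], y2[1])  # the independent candidate now outranks
})

test_that("diagonal covariance makes constant-liar equal top-N at any alpha", {
  withr::with_seed(11, {
    S <- matrix(rnorm(5 * 30), 5, 30)
  })
  pred <- ensembleFromScores(S)
  # overwrite the covariance with its diagonal (independent candidates)
  predD <- methods::new("PredictionEnsemble",
                        candidateIds = candidateIds(pred),
                        memberScores = memberScores(pred),
                        consensus = consensus(pred),
                        covariance = diag(diag(covarianceMatrix(pred))))
  top <- selectedIds(topNSelect(predD, 10))
  for (alpha in c(0.5, 6, 100))
    expect_identical(selectedIds(constantLiarSelect(predD, 10, alpha)), top)
})

test_that("constant-liar converges to exact top-N as alpha grows", {
  matchAt <- function(alpha) {
    mean(vapply(1:40, function(s) {
      S <- withr::with_seed(s, {
        mu <- rnorm(50)
        t(vapply(1:5, function(k) mu + rnorm(50, sd = 0.25), numeric(50)))
      })
      pred <- ensembleFromScores(S)
      setequal(selectedIds(constantLiarSelect(pred, 16, alpha = alpha)),
               selectedIds(topNSelect(pred, 16)))
    }, logical(1)))
  }
  m <- vapply(c(10, 1000, 1e5), matchAt, numeric(1))
  expect_true(all(diff(m) >= 0))   # monotone approach to the limit
  expect_equal(m[3], 1)            # essentially exact at very large alpha
})

test_that("an all-zero covariance falls back to top-N with a warning", {
  pred <- ensembleFromScores(rbind(c(2, 1, 3), c(2, 1, 3)) + 0.0)
  expect_warning(b <- constantLiarSelect(pred, 2, alpha = 6), "top-N")
  expect_identical(selectedIds(b), selectedIds(topNSelect(pred, 2)))
})

test_that("small alpha alternates between correlated clusters", {
  pred <- twoClusterEnsemble(seed = 21)
  aggressive <- constantLiarSelect(pred, 6, alpha = 0.5)
  lociAgg <- unique(substr(selectedIds(aggressive), 2, 2))
  exploit <- constantLiarSelect(pred, 6, alpha = 1000)
  lociExp <- unique(substr(selectedIds(exploit), 2, 2))
  expect_equal(length(lociAgg), 2L)   # both loci visited under a strong lie
  expect_equal(length(lociExp), 1L)   # pure exploitation stays in one
  # the selection trace records the posterior mean at pick time
  expect_length(selectionTrace(aggressive), 6L)
})

test_that("random selection is seeded, distinct and uniform", {
  pool <- paste0("m", 1:100)
  b <- randomSelect(pool, 16, seed = 5)
  expect_length(unique(selectedIds(b)), 16L)
  expect_identical(selectedIds(randomSelect(pool, 16, seed = 5)),
                   selectedIds(b))
  expect_warning(randomSelect(pool[1:4], 16, seed = 1), "pool")
  # frequency of each id over many draws is binomial around 16/100
  counts <- integer(100)
  names(counts) <- pool
  nDraw <- 2000
  for (s in seq_len(nDraw)) {
    ids <- selectedIds(randomSelect(pool, 16, seed = s))
    counts[ids] <- counts[ids] + 1L
  }
  p <- 16 / 100
  se <- sqrt(p * (1 - p) / nDraw)
  expect_true(all(abs(counts / nDraw - p) < 4 * se))
})

test_that("diversity reports count unique and newly explored loci", {
  b1 <- paste0("A", 1:16, "C")  # 16 singles at 16 distinct loci (wt all A)
  r1 <- diversityReport(b1)
  expect_equal(r1@uniqueLoci, 16L)
  expect_equal(r1@newLoci, 16L)
  sameLocus <- paste0("A1", setdiff(AA_ALPHABET, "A")[1:16])
  expect_equal(diversityReport(sameLocus)@uniqueLoci, 1L)
  # a batch whose loci were all seen before explores nothing new
  r2 <- diversityReport(paste0("A", 3:6, "D"), history = list(b1))
  expect_equal(r2@uniqueLoci, 4L)
  expect_equal(r2@newLoci, 0L)
})
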