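test_that("synthetic landscape enumerates singles and anchors wild type at 0", {
  orc <- cleanOracle(L = 10, dim = 8)
  ls1 <- generateLandscape(orc)
  expect_equal(nrow(records(ls1)), 10L * 19L)
  # noiseless activity equals the effect table entry; wild-type letters are 0
  eff <- oracleEffects(orc)
  rec <- records(ls1)
  m <- parseMutationString(rec$mutant[37])
  expect_equal(rec$activity[37],
               unname(eff[m$position, m$mut]))
  wtIdx <- match(strsplit(wildType(orc), "")[[1]], AA_ALPHABET)
  expect_equal(unname(eff[cbind(1:10, wtIdx)]), rep(0, 10))
})

test_that("noise-free additive landscapes make doubles the sum of singles", {
  orc <- syntheticOracle(oracleConfig(L = 12, dim = 8, epistasisWeight = 0,
                                      noiseSd = 0, nDoubles = 40, seed = 5))
  ls1 <- generateLandscape(orc)
  rec <- records(ls1)
  doubles <- rec[rec$nMutations == 2L, ]
  expect_gt(nrow(doubles), 0L)
  a <- activities(ls1)
  for (i in seq_len(nrow(doubles))) {
    toks <- strsplit(doubles$mutant[i], ":", fixed = TRUE)[[1]]
    expect_equal(doubles$activity[i], unname(a[toks[1]] + a[toks[2]]),
                 tolerance = 1e-12)
  }
})

test_that("the oracle is bit-reproducible under its seed", {
  cfg <- oracleConfig(L = 15, dim = 16, nDoubles = 10, epistasisWeight = 0.3,
                      seed = 42)
  o1 <- syntheticOracle(cfg)
  o2 <- syntheticOracle(cfg)
  expect_identical(wildType(o1), wildType(o2))
  expect_identical(oracleEffects(o1), oracleEffects(o2))
  expect_identical(records(generateLandscape(o1)),
                   records(generateLandscape(o2)))
  expect_identical(embedSequences(o1, wildType(o1)),
                   embedSequences(o2, wildType(o2)))
})

test_that("log-probability rows are distributions; rho=1 without noise is a monotone map", {
  orc <- cleanOracle(L = 20, dim = 8)
  lp <- logProbMatrix(orc)
  expect_true(all(abs(rowSums(exp(lp@values)) - 1) < 1e-6))
  nat <- naturalnessEntries(naturalnessTable(lp))
  act <- activities(generateLandscape(orc), nat$id)
  expect_equal(cor(nat$naturalness, act, method = "spearman"), 1)
})

test_that("naturalness-activity correlation is calibrated to the target rho", {
  rhos <- vapply(1:3, function(s) {
    orc <- syntheticOracle(oracleConfig(L = 100, dim = 8,
                                        naturalnessRho = 0.5,
                                        noiseSd = 0.1, seed = s))
    nat <- naturalnessEntries(naturalnessTable(logProbMatrix(orc)))
    act <- activities(generateLandscape(orc), nat$id)
    cor(nat$naturalness, act, method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0.4)
  expect_lt(mean(rhos), 0.6)
})

test_that("embeddings are deterministic, sized, and linearly informative", {
  orc <- cleanOracle(L = 20, dim = 40)
  wt <- wildType(orc)
  s1 <- applyMutations(wt, paste0(substr(wt, 3, 3), 3, "W"))
  expect_identical(embedSequences(orc, s1), embedSequences(orc, s1))
  expect_equal(ncol(embedSequences(orc, wt)), 40L)

  # signalFraction = 1, no noise: least squares on embeddings recovers the
  # activity ranking of singles essentially perfectly
  ls1 <- generateLandscape(orc)
  rec <- records(ls1)
  X <- folde:::.embedIds(orc, wt, rec$id)
  fit <- stats::lm.fit(cbind(1, X), rec$activity)
  beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  pred <- cbind(1, X) %*% beta
  expect_gt(cor(pred, rec$activity, method = "spearman"), 0.99)
})

test_that("embedding informativeness increases with signalFraction", {
  heldoutRho <- function(sf) {
    orc <- syntheticOracle(oracleConfig(L = 20, dim = 24, naturalnessRho = 1,
                                        signalFraction = sf, noiseSd = 0,
                                        seed = 9))
    ls1 <- generateLandscape(orc)
    rec <- records(ls1)
    X <- folde:::.embedIds(orc, wildType(orc), rec$id)
    trainIdx <- withr::with_seed(1, sample(nrow(rec), 120))
    fit <- stats::lm.fit(cbind(1, X[trainIdx, ]), rec$activity[trainIdx])
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    pred <- cbind(1, X[-trainIdx, ]) %*% beta
    cor(pred, rec$activity[-trainIdx], method = "spearman")
  }
  expect_gt(heldoutRho(1.0), heldoutRho(0.25))
})
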