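# Shared fixtures: small oracles/landscapes built in code, plus an
# independent Gaussian-conditioning oracle used by the acquisition tests.

# Desk-scale training configuration (reduced dims; schedule as shipped).
testTrainConfig <- function(dim = 32L, hidden = c(16L, 8L),
                            maxPairs = 2000L, warmstartCap = 150L,
                            pairBatchSize = 64L, ...) {
  trainConfig(inputDim = dim, hiddenDims = hidden, maxPairs = maxPairs,
              warmstartCap = warmstartCap, pairBatchSize = pairBatchSize,
              ...)
}

# A clean, fully informative fixture: naturalness ranks activity exactly,
# embeddings carry the full effect signal, no measurement noise.
cleanOracle <- function(L = 30L, dim = 32L, seed = 3L, ...) {
  syntheticOracle(oracleConfig(L = L, dim = dim, naturalnessRho = 1,
                               signalFraction = 1, noiseSd = 0,
                               seed = seed, ...))
}

# The benchmark-condition fixture: naturalness-activity Spearman ~ 0.5.
benchmarkOracle <- function(L = 30L, dim = 32L, seed = 3L, ...) {
  syntheticOracle(oracleConfig(L = L, dim = dim, naturalnessRho = 0.5,
                               signalFraction = 0.8, noiseSd = 0.1,
                               seed = seed, ...))
}

# A valid LogProbMatrix with uniform rows for a given wild type.
uniformLogProbs <- function(wt) {
  L <- nchar(wt)
  v <- matrix(log(1 / 20), L, 20, dimnames = list(NULL, folde::AA_ALPHABET))
  methods::new("LogProbMatrix", values = v, wildType = wt)
}

# Random valid LogProbMatrix (Dirichlet-ish rows via normalised gammas).
randomLogProbs <- function(wt, seed = 1L) {
  L <- nchar(wt)
  withr::with_seed(seed, {
    p <- matrix(stats::rgamma(L * 20, shape = 1), L, 20)
    p <- p / rowSums(p)
  })
  v <- log(p) - log(rowSums(p))  # exact renormalisation
  dimnames(v) <- list(NULL, folde::AA_ALPHABET)
  methods::new("LogProbMatrix", values = v, wildType = wt)
}

# Random symmetric PSD matrix with strictly positive diagonal.
randomPsd <- function(n, seed) {
  withr::with_seed(seed, {
    A <- matrix(stats::rnorm(n * n), n)
    A %*% t(A) + diag(0.1, n)
  })
}

# Independent oracle for Gaussian conditioning on coordinate i: the
# precision-matrix (block-inverse) route, not the rank-one update.
conditionOracle <- function(y, Sigma, i, yObs) {
  P <- solve(Sigma)
  Prr <- P[-i, -i, drop = FALSE]
  condCov <- solve(Prr)
  condMean <- y[-i] - solve(Prr, P[-i, i]) * (yObs - y[i])
  list(mean = as.numeric(condMean), cov = condCov)
}

# Assemble a PredictionEnsemble from a raw member-score matrix.
ensembleFromScores <- function(S, ids = paste0("c", seq_len(ncol(S)))) {
  S <- S - rowMeans(S)
  D <- sweep(S, 2, colMeans(S))
  methods::new("PredictionEnsemble", candidateIds = ids,
               memberScores = S, consensus = colMeans(S),
               covariance = crossprod(D) / (nrow(S) - 1))
}

# Two-cluster correlated ensemble over single mutants at two loci of "AC".
# Within-cluster scores are driven by a shared per-member offset, so the
# across-member covariance couples candidates at the same locus.
twoClusterEnsemble <- function(seed, perCluster = 8L, nMembers = 5L,
                               gap = 0.3) {
  ids <- c(paste0("A1", setdiff(folde::AA_ALPHABET, "A")[seq_len(perCluster)]),
           paste0("C2", setdiff(folde::AA_ALPHABET, "C")[seq_len(perCluster)]))
  withr::with_seed(seed, {
    mu <- c(stats::rnorm(perCluster, gap, 0.05),
            stats::rnorm(perCluster, 0, 0.05))
    S <- t(vapply(seq_len(nMembers), function(k) {
      off <- stats::rnorm(2, 0, 1)
      mu + rep(off, each = perCluster) + stats::rnorm(length(mu), 0, 0.02)
    }, numeric(length(mu))))
  })
  ensembleFromScores(S, ids)
}
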