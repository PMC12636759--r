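# Synthetic fitness landscape + synthetic language-model oracle.
#
# The oracle plays two roles at once: the "assay" (a ground-truth landscape
# of per-position effects, optional pairwise epistasis and measurement
# noise) and the "language model" (per-position amino-acid log-probabilities
# whose implied naturalness correlates with activity at a configurable
# Spearman rho, plus deterministic sequence embeddings). Everything is a
# pure function of the seed, so downstream stages are testable bit-for-bit
# with no model download.

#' Synthetic oracle configuration
#'
#' @param L Wild-type length (>= 2).
#' @param effectScale Standard deviation of per-(position, amino acid)
#'   activity effects (activity units; the wild type is anchored at 0).
#' @param epistasisWeight Share of a double mutant's activity variance
#'   carried by pairwise interaction terms, in `[0, 1)`.
#' @param noiseSd Measurement noise standard deviation.
#' @param naturalnessRho Target Spearman correlation between single-mutant
#'   naturalness and measured activity, in `(0, 1]`. The log-probability
#'   logits are calibrated so the realised correlation over all single
#'   mutants lands near this value (within about 0.1 for L >= 50).
#' @param dim Embedding length (default 960, the width of the
#'   mean-pooled language-model embeddings the real workflow uses).
#' @param signalFraction Fraction of embedding coordinates that are linear
#'   reads of the mutant's per-position effects; the remainder is a seeded
#'   random projection of sequence content. In `(0, 1]`.
#' @param nDoubles Number of double mutants to sample into the landscape
#'   (0 for singles only).
#' @param seed Integer master seed.
#' @return Named list of validated settings.
#' @export
oracleConfig <- function(L = 100L, effectScale = 1, epistasisWeight = 0,
                         noiseSd = 0.1, naturalnessRho = 0.5, dim = 960L,
                         signalFraction = 0.5, nDoubles = 0L, seed = 1L) {
  cfg <- list(L = as.integer(L), effectScale = effectScale,
              epistasisWeight = epistasisWeight, noiseSd = noiseSd,
              naturalnessRho = naturalnessRho, dim = as.integer(dim),
              signalFraction = signalFraction, nDoubles = as.integer(nDoubles),
              seed = as.integer(seed))
  stopifnot(cfg$L >= 2L, cfg$effectScale > 0,
            cfg$epistasisWeight >= 0, cfg$epistasisWeight < 1,
            cfg$noiseSd >= 0,
            cfg$naturalnessRho > 0, cfg$naturalnessRho <= 1,
            cfg$dim >= 1L,
            cfg$signalFraction > 0, cfg$signalFraction <= 1,
            cfg$nDoubles >= 0L)
  cfg
}

#' Build a deterministic synthetic oracle
#'
#' @param config A list from [oracleConfig()] (or arguments passed on to
#'   it via `...`).
#' @param ... Passed to [oracleConfig()] when `config` is missing.
#' @return A [SyntheticOracle-class].
#' @examples
#' orc <- syntheticOracle(oracleConfig(L = 10, dim = 16, seed = 7))
#' generateLandscape(orc)
#' @export
syntheticOracle <- function(config = oracleConfig(...), ...) {
  L <- config$L
  withSeed(config$seed, {
    wt <- paste(sample(AA_ALPHABET, L, replace = TRUE), collapse = "")
    wtIdx <- match(strsplit(wt, "")[[1]], AA_ALPHABET)

    effects <- matrix(stats::rnorm(L * 20, sd = config$effectScale),
                      nrow = L, ncol = 20, dimnames = list(NULL, AA_ALPHABET))
    effects[cbind(seq_len(L), wtIdx)] <- 0

    interactions <- list(pairs = data.frame(p1 = integer(), p2 = integer(),
                                            s = numeric()),
                         z = matrix(0, 0, 0))
    if (config$epistasisWeight > 0 && L >= 3L) {
      allPairs <- utils::combn(L, 2L)
      nActive <- max(1L, round(0.2 * ncol(allPairs)))
      act <- allPairs[, sample(ncol(allPairs), nActive), drop = FALSE]
      w <- config$epistasisWeight
      # active pairs carry all interaction variance; scale so the average
      # over all position pairs matches the requested share
      s2 <- (2 * config$effectScale^2 * w / (1 - w)) /
        (nActive / ncol(allPairs))
      z <- matrix(stats::rnorm(L * 20), nrow = L, ncol = 20,
                  dimnames = list(NULL, AA_ALPHABET))
      z[cbind(seq_len(L), wtIdx)] <- 0
      interactions <- list(
        pairs = data.frame(p1 = act[1, ], p2 = act[2, ],
                           s = sqrt(s2) * sample(c(-1, 1), nActive,
                                                 replace = TRUE)),
        z = z)
    }

    lp <- .calibrateLogProbs(wt, wtIdx, effects, config)

    dSig <- max(1L, round(config$signalFraction * config$dim))
    dNoise <- config$dim - dSig
    signalProj <- matrix(stats::rnorm(dSig * L, sd = 1 / sqrt(L)),
                         nrow = dSig, ncol = L)
    noiseProj <- if (dNoise > 0)
      matrix(stats::rnorm(dNoise * 20L * L, sd = 1 / sqrt(20 * L)),
             nrow = dNoise, ncol = 20L * L)
    else matrix(0, 0L, 20L * L)

    methods::new("SyntheticOracle", config = config, wildType = wt,
                 effects = effects, interactions = interactions,
                 logProbs = lp, signalProj = signalProj,
                 noiseProj = noiseProj, cache = new.env(parent = emptyenv()))
  })
}

# Logits per position: beta * (effect + eps), eps zeroed at the wild-type
# letter so that naturalness(p, a) = beta * (E[p,a] + eps[p,a]) exactly
# (the softmax normaliser cancels in the log-ratio). eps variance is chosen
# so corr(E + eps, E + measurement noise) hits the Pearson equivalent of
# the target Spearman rho under the bivariate-normal relation
# r = 2 sin(pi * rho / 6).
.calibrateLogProbs <- function(wt, wtIdx, effects, config) {
  L <- config$L
  vE <- config$effectScale^2
  vNoise <- config$noiseSd^2
  r <- 2 * sin(pi * config$naturalnessRho / 6)
  denom <- r^2 * (1 + vNoise / vE)
  vEps <- if (denom >= 1) 0 else vE * (1 / denom - (1 + vNoise / vE))
  vEps <- max(0, vEps)
  eps <- matrix(stats::rnorm(L * 20, sd = sqrt(vEps)), nrow = L, ncol = 20)
  eps[cbind(seq_len(L), wtIdx)] <- 0
  beta <- 1 / config$effectScale
  logits <- beta * (effects + eps)
  logp <- logits - apply(logits, 1, function(x) max(x) + log(sum(exp(x - max(x)))))
  dimnames(logp) <- list(NULL, AA_ALPHABET)
  methods::new("LogProbMatrix", values = logp, wildType = wt)
}

setMethod("show", "SyntheticOracle", function(object) {
  cfg <- object@config
  cat("SyntheticOracle: L=", cfg$L, ", dim=", cfg$dim,
      ", naturalnessRho=", cfg$naturalnessRho,
      ", signalFraction=", cfg$signalFraction,
      ", epistasisWeight=", cfg$epistasisWeight,
      ", seed=", cfg$seed, "\n", sep = "")
})

#' @rdname embedder-contract
setMethod("embedDim", "SyntheticOracle", function(x) x@config$dim)

#' @rdname embedder-contract
setMethod("logProbMatrix", "SyntheticOracle", function(x) x@logProbs)

#' @rdname embedder-contract
setMethod("embedSequences", "SyntheticOracle", function(x, sequences) {
  out <- matrix(NA_real_, nrow = length(sequences), ncol = x@config$dim)
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    hit <- x@cache[[s]]
    if (is.null(hit)) {
      hit <- .embedOne(x, s)
      assign(s, hit, envir = x@cache)
    }
    out[i, ] <- hit
  }
  rownames(out) <- names(sequences)
  out
})

.embedOne <- function(oracle, sequence) {
  L <- oracle@config$L
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) != L) stop("sequence length must equal L = ", L)
  aaIdx <- match(chars, AA_ALPHABET)
  if (anyNA(aaIdx)) stop("non-canonical letter in sequence")
  effVec <- oracle@effects[cbind(seq_len(L), aaIdx)]
  sig <- as.numeric(oracle@signalProj %*% effVec)
  if (nrow(oracle@noiseProj) > 0L) {
    onehot <- numeric(20L * L)
    onehot[(seq_len(L) - 1L) * 20L + aaIdx] <- 1
    c(sig, as.numeric(oracle@noiseProj %*% onehot))
  } else sig
}

# Ground-truth (noise-free) activity of arbitrary mutation sets.
.trueActivity <- function(oracle, mutationList) {
  vapply(mutationList, function(df) {
    aaIdx <- match(df$mut, AA_ALPHABET)
    add <- sum(oracle@effects[cbind(df$position, aaIdx)])
    inter <- 0
    pr <- oracle@interactions$pairs
    if (nrow(pr) > 0L && nrow(df) >= 2L) {
      z <- oracle@interactions$z
      cmb <- utils::combn(nrow(df), 2L)
      for (k in seq_len(ncol(cmb))) {
        i <- cmb[1, k]; j <- cmb[2, k]
        p1 <- min(df$position[i], df$position[j])
        p2 <- max(df$position[i], df$position[j])
        hit <- pr$s[pr$p1 == p1 & pr$p2 == p2]
        if (length(hit) == 1L) {
          zi <- z[df$position[i], match(df$mut[i], AA_ALPHABET)]
          zj <- z[df$position[j], match(df$mut[j], AA_ALPHABET)]
          inter <- inter + hit * zi * zj
        }
      }
    }
    add + inter
  }, numeric(1))
}

#' Generate the synthetic landscape of an oracle
#'
#' Enumerates all `L x 19` single mutants and, if configured, a seeded
#' sample of double mutants. A mutant's activity is the sum of its
#' per-(position, amino acid) effects, plus pairwise interaction terms on
#' the seeded subset of epistatic position pairs, plus i.i.d. measurement
#' noise. The wild type has activity 0 by construction, so "above wild
#' type" is a meaningful hit criterion.
#'
#' @param oracle A [SyntheticOracle-class].
#' @return A [Landscape-class]; ids are the mutation strings.
#' @export
generateLandscape <- function(oracle) {
  cfg <- oracle@config
  L <- cfg$L
  wtChars <- strsplit(oracle@wildType, "")[[1]]
  singles <- do.call(rbind, lapply(seq_len(L), function(p) {
    muts <- setdiff(AA_ALPHABET, wtChars[p])
    data.frame(wt = wtChars[p], position = p, mut = muts,
               stringsAsFactors = FALSE)
  }))
  singleStrings <- paste0(singles$wt, singles$position, singles$mut)
  mutList <- split(singles, seq_len(nrow(singles)))

  doubleStrings <- character(0)
  if (cfg$nDoubles > 0L) {
    withSeed(cfg$seed + 1L, {
      p1 <- sample(L, cfg$nDoubles, replace = TRUE)
      off <- sample(L - 1L, cfg$nDoubles, replace = TRUE)
      p2 <- ((p1 - 1L + off) %% L) + 1L
      lo <- pmin(p1, p2); hi <- pmax(p1, p2)
      a1 <- vapply(lo, function(p)
        sample(setdiff(AA_ALPHABET, wtChars[p]), 1L), character(1))
      a2 <- vapply(hi, function(p)
        sample(setdiff(AA_ALPHABET, wtChars[p]), 1L), character(1))
      doubleStrings <- unique(paste0(wtChars[lo], lo, a1, ":",
                                     wtChars[hi], hi, a2))
    })
    mutList <- c(mutList, parseMutations(doubleStrings))
  }

  act <- .trueActivity(oracle, mutList)
  if (cfg$noiseSd > 0)
    act <- act + withSeed(cfg$seed + 2L,
                          stats::rnorm(length(act), sd = cfg$noiseSd))
  Landscape(wildType = oracle@wildType,
            mutants = c(singleStrings, doubleStrings),
            activity = act,
            name = paste0("synthetic-L", L, "-seed", cfg$seed))
}

#' Per-position effect table of a synthetic oracle
#'
#' @param oracle A [SyntheticOracle-class].
#' @return The L x 20 matrix of ground-truth effects (0 at wild-type
#'   letters).
#' @export
oracleEffects <- function(oracle) oracle@effects
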