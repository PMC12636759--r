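# Central S4 classes. Validity methods enforce the invariants the rest of
# the package relies on; constructors live in the module files.

#' Canonical amino-acid alphabet
#'
#' The 20 standard amino acids in alphabetical one-letter order. All
#' position-by-residue matrices in the package (log-probabilities, effect
#' tables) use this column ordering.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Landscape: a wild type plus mutants with ground-truth activities
#'
#' The simulation oracle of the benchmark: a wild-type sequence and a table
#' of mutant records with measured (ground-truth) activities, as in a deep
#' mutational scanning dataset. Row ids double as mutation strings
#' (`"A24G"`, `"A24G:T56C"`) unless the source file supplies its own ids.
#'
#' @slot wildType Amino-acid string of length L.
#' @slot records `data.frame` with columns `id` (unique), `mutant`
#'   (colon-separated mutation string), `activity` (numeric ground truth)
#'   and `nMutations` (integer).
#' @slot name Label for the landscape.
#' @name Landscape-class
#' @exportClass Landscape
setClass("Landscape",
  representation(wildType = "character", records = "data.frame",
                 name = "character"))

setValidity("Landscape", function(object) {
  wt <- object@wildType
  rec <- object@records
  msg <- character()
  if (length(wt) != 1L || nchar(wt) < 1L)
    msg <- c(msg, "wildType must be a single non-empty string")
  need <- c("id", "mutant", "activity", "nMutations")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(rec$id))
    msg <- c(msg, "record ids must be unique")
  if (nrow(rec) > 0L) {
    wtChars <- strsplit(wt, "")[[1]]
    muts <- parseMutations(rec$mutant)
    pos <- unlist(lapply(muts, `[[`, "position"), use.names = FALSE)
    wtaa <- unlist(lapply(muts, `[[`, "wt"), use.names = FALSE)
    if (length(pos) && max(pos) > nchar(wt))
      msg <- c(msg, "mutation position beyond wild-type length")
    else if (length(pos) && any(wtChars[pos] != wtaa))
      msg <- c(msg, "mutation wt letter disagrees with wild-type sequence")
  }
  if (length(msg)) msg else TRUE
})

#' Accessible / held-out partition of a landscape
#'
#' @slot accessibleIds,heldOutIds Disjoint character vectors of record ids
#'   whose union covers the landscape.
#' @slot seed Integer seed the split was drawn with.
#' @name HoldoutSplit-class
#' @exportClass HoldoutSplit
setClass("HoldoutSplit",
  representation(accessibleIds = "character", heldOutIds = "character",
                 seed = "integer"))

setValidity("HoldoutSplit", function(object) {
  if (length(intersect(object@accessibleIds, object@heldOutIds)) > 0L)
    return("accessible and held-out ids overlap")
  TRUE
})

#' Per-position amino-acid log-probabilities
#'
#' Stand-in for a protein language model's output head: an L x 20 matrix of
#' log-probabilities conditioned on the (unmasked) wild-type sequence, with
#' columns in [AA_ALPHABET] order. Each row exponentiates to a probability
#' distribution.
#'
#' @slot values Numeric L x 20 matrix of finite log-probabilities.
#' @slot wildType The conditioning sequence (length L).
#' @name LogProbMatrix-class
#' @exportClass LogProbMatrix
setClass("LogProbMatrix",
  representation(values = "matrix", wildType = "character"))

setValidity("LogProbMatrix", function(object) {
  v <- object@values
  if (ncol(v) != 20L || !identical(colnames(v), AA_ALPHABET))
    return("values must have 20 columns named by AA_ALPHABET")
  if (nrow(v) != nchar(object@wildType))
    return("row count must equal wild-type length")
  if (!all(is.finite(v)))
    return("log-probabilities must be finite")
  s <- rowSums(exp(v))
  if (any(abs(s - 1) > 1e-6))
    return("each row must exponentiate and sum to 1 (tolerance 1e-6)")
  TRUE
})

#' Naturalness scores of all single mutants
#'
#' One entry per (position, substituted amino acid) pair: the log-likelihood
#' ratio of mutant to wild type at that position. L x 19 entries for a
#' wild type of length L.
#'
#' @slot entries `data.frame` with columns `id` (mutation string),
#'   `position`, `mutAa`, `naturalness`.
#' @slot wildType The reference sequence.
#' @name NaturalnessTable-class
#' @exportClass NaturalnessTable
setClass("NaturalnessTable",
  representation(entries = "data.frame", wildType = "character"))

setValidity("NaturalnessTable", function(object) {
  e <- object@entries
  need <- c("id", "position", "mutAa", "naturalness")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns:", paste(need, collapse = ", ")))
  if (!all(is.finite(e$naturalness)))
    return("naturalness values must be finite")
  wtChars <- strsplit(object@wildType, "")[[1]]
  if (nrow(e) && any(wtChars[e$position] == e$mutAa))
    return("entries must not include the wild-type letter")
  if (anyDuplicated(e[c("position", "mutAa")]))
    return("duplicate (position, mutAa) entries")
  TRUE
})

#' Virtual embedder class
#'
#' See [embedder-contract] for the generics an embedder implements.
#'
#' @name Embedder-class
#' @exportClass Embedder
setClass("Embedder", representation("VIRTUAL"))

#' Deterministic synthetic sequence oracle
#'
#' A seeded stand-in for a protein language model and an assay at once: it
#' defines a ground-truth fitness landscape (additive per-position effects,
#' optional pairwise epistasis, measurement noise), per-position amino-acid
#' log-probabilities whose implied naturalness correlates with activity at a
#' configurable Spearman rho, and deterministic sequence embeddings a
#' ranking model can learn from. Created by [syntheticOracle()].
#'
#' @slot config Named list of generator settings (see [oracleConfig()]).
#' @slot wildType The wild-type sequence (activity anchored at 0).
#' @slot effects L x 20 matrix of per-(position, amino acid) activity
#'   effects; 0 at the wild-type letter of each position.
#' @slot interactions List with the seeded pairwise-epistasis structure
#'   (`pairs`: data.frame of active position pairs and their coefficient;
#'   `z`: L x 20 matrix of per-residue loadings).
#' @slot logProbs [LogProbMatrix-class] calibrated to the target
#'   naturalness-activity correlation.
#' @slot signalProj,noiseProj Seeded projection matrices behind the
#'   embedding map.
#' @slot cache Environment memoising embeddings by sequence.
#' @name SyntheticOracle-class
#' @exportClass SyntheticOracle
setClass("SyntheticOracle", contains = "Embedder",
  representation(config = "list", wildType = "character",
                 effects = "matrix", interactions = "list",
                 logProbs = "LogProbMatrix", signalProj = "matrix",
                 noiseProj = "matrix", cache = "environment"))

#' Directed ranking pairs split into train and validation
#'
#' Winner-first directed pairs partitioned 80-20 such that no validation
#' pair is implied by transitivity of the train pairs (checked by
#' breadth-first search over the train digraph).
#'
#' @slot trainPairs,valPairs `data.frame`s with columns `winner`, `loser`.
#' @slot seed Integer seed of the shuffle.
#' @slot quota The targeted validation size (may exceed `nrow(valPairs)` on
#'   dense digraphs where the constraint leaves too few eligible pairs).
#' @name PairSplit-class
#' @exportClass PairSplit
setClass("PairSplit",
  representation(trainPairs = "data.frame", valPairs = "data.frame",
                 seed = "integer", quota = "integer"))

#' Training configuration of a ranking-ensemble member
#'
#' Defaults follow the reference architecture: a 960 -> 100 -> 50 -> 1
#' multilayer perceptron with batch normalisation after each hidden layer,
#' ReLU activations, dropout 0.2, no bias in the final layer, Adam with
#' learning rate 3e-4 and weight decay 1e-5; warm-start runs at most 50
#' epochs (patience 20, validation every 5), activity training at most 200
#' epochs (patience 40, validation every 10). Built by [trainConfig()].
#'
#' @name TrainConfig-class
#' @exportClass TrainConfig
setClass("TrainConfig", representation(values = "list"))

setValidity("TrainConfig", function(object) {
  v <- object@values
  pos <- c("inputDim", "dropout", "lr", "weightDecay", "warmstartMaxEpochs",
           "warmstartPatience", "warmstartValEvery", "activityMaxEpochs",
           "activityPatience", "activityValEvery", "pairBatchSize",
           "maxPairs", "warmstartCap")
  bad <- pos[!vapply(v[pos], function(x) is.numeric(x) && x > 0, logical(1))]
  if (length(bad))
    return(paste("non-positive config values:", paste(bad, collapse = ", ")))
  if (v$dropout >= 1) return("dropout must be in [0, 1)")
  if (v$warmstartPatience > v$warmstartMaxEpochs ||
      v$activityPatience > v$activityMaxEpochs)
    return("patience must not exceed the maximum epoch count")
  if (!all(v$hiddenDims >= 1)) return("hiddenDims must be positive")
  TRUE
})

#' Ensemble of trained ranking members
#'
#' @slot members List of trained members (internal MLP state).
#' @slot config The [TrainConfig-class] used.
#' @slot seeds Integer vector of distinct member seeds.
#' @name RankerEnsemble-class
#' @exportClass RankerEnsemble
setClass("RankerEnsemble",
  representation(members = "list", config = "TrainConfig", seeds = "integer"))

setValidity("RankerEnsemble", function(object) {
  if (anyDuplicated(object@seeds)) return("member seeds must be distinct")
  if (length(object@members) != length(object@seeds))
    return("one seed per member required")
  TRUE
})

#' Ensemble predictions over a candidate set
#'
#' Per-member scores demeaned over the candidate set (Bradley-Terry scores
#' are translation-invariant, so only the within-member centring makes
#' members comparable), their mean as the consensus, and the across-member
#' covariance used by constant-liar acquisition.
#'
#' @slot candidateIds Ordered character vector of N candidate ids.
#' @slot memberScores K x N matrix; each row has mean 0.
#' @slot consensus Length-N column mean of `memberScores`.
#' @slot covariance N x N across-member covariance (1/(K-1) normalisation);
#'   symmetric, positive semidefinite up to numerical tolerance, rank at
#'   most K-1.
#' @name PredictionEnsemble-class
#' @exportClass PredictionEnsemble
setClass("PredictionEnsemble",
  representation(candidateIds = "character", memberScores = "matrix",
                 consensus = "numeric", covariance = "matrix"))

setValidity("PredictionEnsemble", function(object) {
  n <- length(object@candidateIds)
  S <- object@memberScores
  if (ncol(S) != n) return("memberScores must have one column per candidate")
  if (length(object@consensus) != n) return("consensus length mismatch")
  if (!all(dim(object@covariance) == c(n, n)))
    return("covariance must be N x N")
  if (n > 0L && any(abs(rowMeans(S)) > 1e-8))
    return("member score rows must be demeaned (|mean| <= 1e-8)")
  if (any(abs(object@covariance - t(object@covariance)) > 1e-8))
    return("covariance must be symmetric")
  TRUE
})

#' A selected batch of mutants
#'
#' @slot selectedIds Ordered ids, no duplicates.
#' @slot selectionTrace Posterior mean of each pick at the time it was
#'   chosen (equals the consensus for non-sequential strategies; NA for
#'   random selection).
#' @name Batch-class
#' @exportClass Batch
setClass("Batch",
  representation(selectedIds = "character", selectionTrace = "numeric"))

setValidity("Batch", function(object) {
  if (anyDuplicated(object@selectedIds)) return("duplicate ids in batch")
  if (length(object@selectionTrace) != length(object@selectedIds))
    return("selectionTrace must align with selectedIds")
  TRUE
})

#' Batch diversity accounting
#'
#' @slot uniqueLoci Distinct mutated positions in the batch.
#' @slot newLoci Positions not mutated in any earlier batch of the campaign.
#' @name DiversityReport-class
#' @exportClass DiversityReport
setClass("DiversityReport",
  representation(uniqueLoci = "integer", newLoci = "integer"))

setValidity("DiversityReport", function(object) {
  if (object@newLoci > object@uniqueLoci)
    return("newLoci cannot exceed uniqueLoci")
  TRUE
})

#' Campaign configuration
#'
#' Built by [campaignConfig()]; defaults mirror the benchmark protocol:
#' 3 rounds of 16 mutants, 50% holdout, zero-shot round 1, warm-started
#' Bradley-Terry ensemble with constant-liar batches (alpha = 6 in round 2,
#' 100 from round 3 on, i.e. near-pure exploitation).
#'
#' @name CampaignConfig-class
#' @exportClass CampaignConfig
setClass("CampaignConfig", representation(values = "list"))

setValidity("CampaignConfig", function(object) {
  v <- object@values
  if (v$rounds < 1L) return("rounds must be >= 1")
  if (v$batchSize < 1L) return("batchSize must be >= 1")
  if (!v$strategy %in% c("folde", "random", "zero_shot", "random_forest"))
    return("unknown strategy")
  if (v$rounds >= 2L) {
    need <- as.character(2:v$rounds)
    if (!all(need %in% names(v$alphaSchedule)))
      return("alphaSchedule must cover every round >= 2")
    if (any(v$alphaSchedule[need] <= 0)) return("alpha values must be > 0")
  }
  if (v$holdoutFraction <= 0 || v$holdoutFraction >= 1)
    return("holdoutFraction must be in (0, 1)")
  TRUE
})

#' Result of one simulated campaign round
#'
#' @slot roundIndex 1-based round number.
#' @slot selected The [Batch-class] chosen this round.
#' @slot measurements Named numeric: oracle activities of the selection.
#' @slot heldoutSpearman Spearman correlation of model predictions on a
#'   held-out sample (NA in round 1 and for model-free strategies).
#' @slot diversity A [DiversityReport-class].
#' @name RoundResult-class
#' @exportClass RoundResult
setClass("RoundResult",
  representation(roundIndex = "integer", selected = "Batch",
                 measurements = "numeric", heldoutSpearman = "numeric",
                 diversity = "DiversityReport"))

setValidity("RoundResult", function(object) {
  if (!setequal(names(object@measurements), object@selected@selectedIds))
    return("measurements must exactly cover the selected ids")
  TRUE
})

#' End-of-campaign metrics
#'
#' @slot cumulativeTop10Hits Number of selected mutants at or above the
#'   90th activity percentile of the accessible set.
#' @slot foundTop1 Whether any selected mutant reaches the 99th percentile.
#' @slot perRoundHits Integer vector of top-10% hits per round.
#' @name CampaignMetrics-class
#' @exportClass CampaignMetrics
setClass("CampaignMetrics",
  representation(cumulativeTop10Hits = "integer", foundTop1 = "logical",
                 perRoundHits = "integer"))

setValidity("CampaignMetrics", function(object) {
  if (object@cumulativeTop10Hits != sum(object@perRoundHits))
    return("cumulativeTop10Hits must equal the per-round sum")
  TRUE
})
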