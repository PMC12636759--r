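# The few-shot activity predictor: warm-started Bradley-Terry ranking
# members and the demeaned prediction ensemble with across-member
# covariance.

#' Build a training configuration
#'
#' See [TrainConfig-class] for the architecture and learning protocol the
#' defaults encode. The remaining knobs are implementation scale controls:
#' `pairBatchSize` (pairs per optimisation step), `maxPairs` (the pair
#' universe is subsampled to this size, seeded, before the train/validation
#' split — the all-pairs set grows quadratically in the record count) and
#' `warmstartCap` (maximum number of single mutants used as warm-start
#' targets).
#'
#' @param inputDim Embedding length (default 960).
#' @param hiddenDims Hidden layer widths (default `c(100, 50)`).
#' @param dropout Dropout probability (default 0.2).
#' @param lr,weightDecay Adam learning rate (3e-4) and L2 weight decay
#'   (1e-5).
#' @param warmstartMaxEpochs,warmstartPatience,warmstartValEvery Warm-start
#'   schedule: at most 50 epochs, early stopping patience 20, validation
#'   every 5 epochs.
#' @param activityMaxEpochs,activityPatience,activityValEvery Activity
#'   fine-tuning schedule: at most 200 epochs, patience 40, validation
#'   every 10.
#' @param pairBatchSize,maxPairs,warmstartCap Scale controls, see above.
#' @return A [TrainConfig-class].
#' @export
trainConfig <- function(inputDim = 960L, hiddenDims = c(100L, 50L),
                        dropout = 0.2, lr = 3e-4, weightDecay = 1e-5,
                        warmstartMaxEpochs = 50L, warmstartPatience = 20L,
                        warmstartValEvery = 5L, activityMaxEpochs = 200L,
                        activityPatience = 40L, activityValEvery = 10L,
                        pairBatchSize = 512L, maxPairs = 20000L,
                        warmstartCap = 2000L) {
  methods::new("TrainConfig", values = list(
    inputDim = as.integer(inputDim), hiddenDims = as.integer(hiddenDims),
    dropout = dropout, lr = lr, weightDecay = weightDecay,
    warmstartMaxEpochs = as.integer(warmstartMaxEpochs),
    warmstartPatience = as.integer(warmstartPatience),
    warmstartValEvery = as.integer(warmstartValEvery),
    activityMaxEpochs = as.integer(activityMaxEpochs),
    activityPatience = as.integer(activityPatience),
    activityValEvery = as.integer(activityValEvery),
    pairBatchSize = as.integer(pairBatchSize),
    maxPairs = as.integer(maxPairs),
    warmstartCap = as.integer(warmstartCap)))
}

#' Configuration values of a TrainConfig
#'
#' @param config A [TrainConfig-class].
#' @return Its named list of settings.
#' @export
trainConfigValues <- function(config) config@values

setMethod("show", "TrainConfig", function(object) {
  v <- object@values
  cat("TrainConfig: ", v$inputDim, " -> ",
      paste(v$hiddenDims, collapse = " -> "), " -> 1 (dropout ",
      v$dropout, ", lr ", v$lr, ")\n", sep = "")
})

#' Create an untrained ranking member
#'
#' @param config A [TrainConfig-class].
#' @param seed Integer seed; initial weights, pair shuffles and dropout of
#'   this member all flow from it.
#' @return An (internal-structure) member list.
#' @export
newRankerMember <- function(config, seed) {
  v <- config@values
  list(layers = mlpInit(v$inputDim, v$hiddenDims, seed),
       seed = as.integer(seed), warmStarted = FALSE,
       history = list())
}

# Core Bradley-Terry trainer shared by warm-start and activity phases.
# targets: named numeric; X: embedding matrix with rownames covering the
# target ids. All randomness is drawn under `phaseSeed`.
.trainBT <- function(member, targets, X, maxEpochs, patience, valEvery,
                     config, phaseSeed) {
  v <- config@values
  ids <- names(targets)
  X <- X[ids, , drop = FALSE]
  withSeed(phaseSeed, {
    pairs <- buildDirectedPairs(targets)
    if (nrow(pairs) == 0L)
      stop("all training targets tied: no ranking pairs")
    if (nrow(pairs) > v$maxPairs)
      pairs <- pairs[sample(nrow(pairs), v$maxPairs), , drop = FALSE]
    degenerate <- nrow(pairs) < 5L
    if (degenerate) {
      foldeLog("fewer than 5 pairs: training without validation")
      tw <- match(pairs$winner, ids); tl <- match(pairs$loser, ids)
      vw <- integer(0); vl <- integer(0)
    } else {
      sp <- splitPairs(pairs, 0.2, seed = sample.int(2^30, 1L))
      tw <- match(sp@trainPairs$winner, ids)
      tl <- match(sp@trainPairs$loser, ids)
      vw <- match(sp@valPairs$winner, ids)
      vl <- match(sp@valPairs$loser, ids)
      if (length(vw) == 0L) degenerate <- TRUE
    }
    if (degenerate) { vw <- integer(0); vl <- integer(0) }
    res <- .cppTrainBT(X, tw - 1L, tl - 1L, vw - 1L, vl - 1L,
                       member$layers, maxEpochs, patience, valEvery,
                       v$pairBatchSize, v$lr, v$weightDecay, v$dropout)
    # compiled code returns 1-column matrices for the vector parameters
    member$layers <- lapply(res$layers, function(ly) {
      ly[names(ly) != "W"] <- lapply(ly[names(ly) != "W"], as.numeric)
      ly
    })
    member$lastHistory <- res$history
    member
  })
}

#' Warm-start a member on the naturalness landscape
#'
#' Pretrains a ranking member to reproduce the naturalness ordering of all
#' single mutants (Bradley-Terry loss on naturalness-derived pairs, early
#' stopping on a transitivity-safe validation split). This exposes the
#' model to the full spectrum of mutant quality before it sees the biased,
#' high-naturalness measurements of round 1.
#'
#' @param member From [newRankerMember()].
#' @param table A [NaturalnessTable-class].
#' @param embeddings Numeric matrix with rownames covering the table ids.
#' @param config A [TrainConfig-class].
#' @return The trained member, with `warmStarted = TRUE` and the training
#'   history under `history$warmstart`.
#' @export
warmStartMember <- function(member, table, embeddings, config) {
  v <- config@values
  e <- table@entries
  if (nrow(e) == 0L) stop("empty naturalness table")
  targets <- stats::setNames(e$naturalness, e$id)
  if (length(targets) > v$warmstartCap)
    targets <- withSeed(deriveSeed(member$seed, 3L),
                        targets[sample(length(targets), v$warmstartCap)])
  member <- .trainBT(member, targets, embeddings,
                     v$warmstartMaxEpochs, v$warmstartPatience,
                     v$warmstartValEvery, config,
                     phaseSeed = deriveSeed(member$seed, 1L))
  member$warmStarted <- TRUE
  member$history$warmstart <- member$lastHistory
  member
}

#' Fine-tune a member on measured activities
#'
#' @param member A (typically warm-started) member.
#' @param measured Named numeric vector of measured activities (>= 2
#'   records with at least two distinct values).
#' @param embeddings Numeric matrix with rownames covering the ids.
#' @param config A [TrainConfig-class].
#' @return The trained member; history under `history$activity`.
#' @export
trainMemberActivity <- function(member, measured, embeddings, config) {
  if (length(measured) < 2L)
    stop("need at least 2 measured records")
  v <- config@values
  member <- .trainBT(member, measured, embeddings,
                     v$activityMaxEpochs, v$activityPatience,
                     v$activityValEvery, config,
                     phaseSeed = deriveSeed(member$seed, 2L))
  member$history$activity <- member$lastHistory
  member
}

#' Train a full ranking ensemble
#'
#' Creates `nMembers` members with seeds `baseSeed + 1 .. baseSeed +
#' nMembers`, optionally warm-starts each on the naturalness table, then
#' fine-tunes each on the measured activities.
#'
#' @param measured Named numeric activities.
#' @param embeddings Matrix with rownames covering measured ids and (when
#'   warm-starting) the naturalness table ids.
#' @param config A [TrainConfig-class].
#' @param table Optional [NaturalnessTable-class]; `NULL` disables the
#'   warm-start.
#' @param nMembers Ensemble size (default 5).
#' @param baseSeed Integer base seed.
#' @return A [RankerEnsemble-class].
#' @export
trainRankerEnsemble <- function(measured, embeddings, config,
                                table = NULL, nMembers = 5L,
                                baseSeed = 1L) {
  seeds <- as.integer(baseSeed + seq_len(nMembers))
  members <- lapply(seeds, function(s) {
    m <- newRankerMember(config, s)
    if (!is.null(table))
      m <- warmStartMember(m, table, embeddings, config)
    trainMemberActivity(m, measured, embeddings, config)
  })
  methods::new("RankerEnsemble", members = members, config = config,
               seeds = seeds)
}

setMethod("show", "RankerEnsemble", function(object) {
  cat("RankerEnsemble: ", length(object@members), " members (seeds ",
      paste(object@seeds, collapse = ", "), ")\n", sep = "")
})

#' Ensemble predictions with across-member covariance
#'
#' Scores every candidate with every member, demeans each member's scores
#' over the candidate set (Bradley-Terry scores are only defined up to a
#' shift), and returns the consensus (column mean) together with the
#' across-member covariance `t(D) D / (K - 1)`, where D holds each demeaned
#' member's deviations from the consensus — the uncertainty substrate of
#' constant-liar acquisition. Members that agree exactly yield a zero
#' covariance.
#'
#' @param ensemble A [RankerEnsemble-class].
#' @param embeddings Candidate embedding matrix (rownames = candidate ids),
#'   or `NULL` to compute it from `sequences` and `embedder`.
#' @param sequences,embedder Candidate sequences plus an
#'   [Embedder-class], used when `embeddings` is `NULL`; ids are taken
#'   from `names(sequences)`.
#' @return A [PredictionEnsemble-class].
#' @export
predictEnsemble <- function(ensemble, embeddings = NULL, sequences = NULL,
                            embedder = NULL) {
  if (is.null(embeddings)) {
    stopifnot(!is.null(sequences), !is.null(embedder))
    embeddings <- embedSequences(embedder, sequences)
    rownames(embeddings) <- names(sequences)
  }
  ids <- rownames(embeddings)
  if (is.null(ids)) stop("embeddings must carry rownames (candidate ids)")
  S <- do.call(rbind, lapply(ensemble@members, function(m)
    mlpPredict(m$layers, embeddings)))
  S <- S - rowMeans(S)
  K <- nrow(S)
  cons <- colMeans(S)
  D <- sweep(S, 2L, cons)  # deviations from the consensus
  methods::new("PredictionEnsemble", candidateIds = ids,
               memberScores = S, consensus = cons,
               covariance = crossprod(D) / (K - 1))
}

#' @rdname accessors
setMethod("candidateIds", "PredictionEnsemble", function(x) x@candidateIds)
#' @rdname accessors
setMethod("memberScores", "PredictionEnsemble", function(x) x@memberScores)
#' @rdname accessors
setMethod("consensus", "PredictionEnsemble", function(x) x@consensus)
#' @rdname accessors
setMethod("covarianceMatrix", "PredictionEnsemble", function(x) x@covariance)

setMethod("show", "PredictionEnsemble", function(object) {
  cat("PredictionEnsemble: ", nrow(object@memberScores), " members x ",
      length(object@candidateIds), " candidates\n", sep = "")
})

#' Save / load an ensemble checkpoint directory
#'
#' Writes one JSON weight file per member plus a manifest (config, seeds,
#' training histories) — a plain-text checkpoint format.
#'
#' @param ensemble A [RankerEnsemble-class].
#' @param dir Checkpoint directory (created if missing).
#' @return `saveRankerEnsemble` returns `dir` invisibly;
#'   `loadRankerEnsemble` the restored [RankerEnsemble-class].
#' @export
saveRankerEnsemble <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = ensemble@config@values,
                   seeds = ensemble@seeds,
                   nMembers = length(ensemble@members))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_along(ensemble@members)) {
    m <- ensemble@members[[k]]
    jsonlite::write_json(
      list(seed = m$seed, warmStarted = m$warmStarted,
           layers = lapply(m$layers, function(ly)
             lapply(ly, function(x) if (is.matrix(x))
               list(dim = dim(x), data = as.numeric(x)) else as.numeric(x)))),
      file.path(dir, sprintf("member_%d.json", k)),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' @rdname saveRankerEnsemble
#' @export
loadRankerEnsemble <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(trainConfig, manifest$config)
  members <- lapply(seq_len(manifest$nMembers), function(k) {
    raw <- jsonlite::read_json(file.path(dir, sprintf("member_%d.json", k)),
                               simplifyVector = TRUE,
                               simplifyDataFrame = FALSE)
    layers <- lapply(raw$layers, function(ly)
      lapply(ly, function(x)
        if (is.list(x)) matrix(x$data, nrow = x$dim[1]) else as.numeric(x)))
    list(layers = layers, seed = as.integer(raw$seed),
         warmStarted = isTRUE(raw$warmStarted), history = list())
  })
  methods::new("RankerEnsemble", members = members, config = cfg,
               seeds = as.integer(manifest$seeds))
}
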