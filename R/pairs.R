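# Directed ranking pairs: construction, the transitivity-aware 80-20
# train/validation split, and the Bradley-Terry loss.

#' Build all directed pairs from scalar targets
#'
#' One winner-first pair per unordered pair of records with strictly
#' different targets; ties produce no pair. Targets enter training only
#' through these orderings, so any strictly monotone transform of the
#' targets yields the same pairs.
#'
#' @param targets Named numeric vector (names are record ids).
#' @return `data.frame` with columns `winner`, `loser`.
#' @export
buildDirectedPairs <- function(targets) {
  ids <- names(targets)
  if (is.null(ids)) stop("targets must be named by record id")
  if (length(targets) < 2L)
    return(data.frame(winner = character(0), loser = character(0),
                      stringsAsFactors = FALSE))
  n <- length(targets)
  a <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  b <- sequence((n - 1L):1L) + a
  ta <- targets[a]; tb <- targets[b]
  keep <- ta != tb
  a <- a[keep]; b <- b[keep]
  swap <- targets[b] > targets[a]
  w <- ifelse(swap, b, a)
  l <- ifelse(swap, a, b)
  data.frame(winner = ids[w], loser = ids[l], stringsAsFactors = FALSE)
}

#' Split directed pairs into train and validation without transitive leakage
#'
#' Shuffles the pairs with the given seed and walks the shuffled order,
#' moving pairs into validation until the 20% quota is met — but rejecting
#' any pair `(a, b)` whose outcome is already implied by the remaining
#' train pairs, i.e. where `b` is reachable from `a` by a directed path in
#' the train digraph (checked by breadth-first search). Rejected pairs stay
#' in train. On dense digraphs the constraint can leave fewer eligible
#' pairs than the quota; the under-fill is logged, not an error.
#'
#' @param pairs `data.frame` from [buildDirectedPairs()] (>= 5 rows).
#' @param valFraction Targeted validation fraction (default 0.2).
#' @param seed Integer shuffle seed.
#' @return A [PairSplit-class].
#' @export
splitPairs <- function(pairs, valFraction = 0.2, seed = 1L) {
  n <- nrow(pairs)
  if (n < 5L) stop("need at least 5 pairs to split")
  quota <- as.integer(round(valFraction * n))
  nodes <- unique(c(pairs$winner, pairs$loser))
  w <- match(pairs$winner, nodes)
  l <- match(pairs$loser, nodes)
  outPairs <- split(seq_len(n), factor(w, levels = seq_along(nodes)))
  inTrain <- rep(TRUE, n)
  isVal <- rep(FALSE, n)
  order <- withSeed(seed, sample(n))
  nVal <- 0L
  for (k in order) {
    if (nVal >= quota) break
    inTrain[k] <- FALSE
    if (!.reachable(w[k], l[k], outPairs, l, inTrain)) {
      isVal[k] <- TRUE
      nVal <- nVal + 1L
    } else {
      inTrain[k] <- TRUE
    }
  }
  if (nVal < quota)
    foldeLog("validation quota under-filled: ", nVal, " of ", quota,
             " (transitivity constraint)")
  methods::new("PairSplit",
               trainPairs = pairs[inTrain, , drop = FALSE],
               valPairs = pairs[isVal, , drop = FALSE],
               seed = as.integer(seed), quota = quota)
}

# BFS over the train digraph: is `to` reachable from `from`?
.reachable <- function(from, to, outPairs, loserOf, inTrain) {
  if (from == to) return(TRUE)
  visited <- logical(length(outPairs))
  visited[from] <- TRUE
  queue <- from
  while (length(queue)) {
    u <- queue[[1]]
    queue <- queue[-1]
    es <- outPairs[[u]]
    es <- es[inTrain[es]]
    for (v in loserOf[es]) {
      if (v == to) return(TRUE)
      if (!visited[v]) {
        visited[v] <- TRUE
        queue <- c(queue, v)
      }
    }
  }
  FALSE
}

#' @rdname accessors
setMethod("trainPairs", "PairSplit", function(x) x@trainPairs)
#' @rdname accessors
setMethod("valPairs", "PairSplit", function(x) x@valPairs)

setMethod("show", "PairSplit", function(object) {
  cat("PairSplit: ", nrow(object@trainPairs), " train / ",
      nrow(object@valPairs), " validation pairs (quota ", object@quota,
      ", seed ", object@seed, ")\n", sep = "")
})

#' Bradley-Terry ranking loss
#'
#' Mean binary cross-entropy between `sigmoid(score difference)` and the
#' pair labels (1 = winner-first orientation, the convention throughout
#' this package). A zero score difference costs `log 2`; the loss is
#' invariant to any common additive shift of the scores — the reason the
#' final network layer carries no bias.
#'
#' @param scoreDiffs Numeric vector of `score(winner) - score(loser)`.
#' @param labels Pair labels (default all 1).
#' @return Mean loss (a single non-negative number).
#' @export
btLoss <- function(scoreDiffs, labels = rep(1, length(scoreDiffs))) {
  stopifnot(length(labels) == length(scoreDiffs))
  mean(ifelse(labels == 1, softplus(-scoreDiffs), softplus(scoreDiffs)))
}
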