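# Batch selection over a prediction ensemble: top-N, constant-liar with
# alpha-scaled stabilisation noise, random baseline, and batch-diversity
# accounting.

#' Top-N batch selection
#'
#' The `batchSize` candidates with the highest consensus mean; ties broken
#' by candidate order (deterministic).
#'
#' @param pred A [PredictionEnsemble-class].
#' @param batchSize Number of picks.
#' @return A [Batch-class] in descending-consensus order.
#' @export
topNSelect <- function(pred, batchSize = 16L) {
  n <- length(pred@candidateIds)
  if (batchSize >= n) {
    ord <- order(-pred@consensus)
  } else {
    ord <- order(-pred@consensus)[seq_len(batchSize)]
  }
  methods::new("Batch", selectedIds = pred@candidateIds[ord],
               selectionTrace = pred@consensus[ord])
}

#' Constant-liar covariance posterior
#'
#' Conditions the across-member covariance on an (imagined) observation of
#' candidate `pickIndex`: `Sigma' = Sigma[-i, -i] - v v^T / sigma_i^2`,
#' with `v` the column coupling the pick to the rest. The update does not
#' depend on the value of the lie. Equals the Gaussian conditional
#' covariance.
#'
#' @param Sigma Symmetric covariance matrix with `Sigma[i, i] > 0` (the
#'   stabilisation jitter guarantees this inside [constantLiarSelect()]).
#' @param pickIndex Index of the conditioned candidate.
#' @return The posterior covariance over the remaining candidates.
#' @export
covariancePosterior <- function(Sigma, pickIndex) {
  s2 <- Sigma[pickIndex, pickIndex]
  if (s2 <= 0) stop("pick variance must be positive (jitter missing?)")
  v <- Sigma[-pickIndex, pickIndex]
  Sigma[-pickIndex, -pickIndex, drop = FALSE] - tcrossprod(v) / s2
}

#' Constant-liar mean posterior
#'
#' The Gaussian conditional mean over the remaining candidates after an
#' imagined observation `yLie` of candidate `pickIndex`:
#' `y' = y[-i] + v (yLie - y[i]) / sigma_i^2`. A lie equal to the current
#' prediction leaves the mean unchanged; uncorrelated candidates
#' (`v = 0`) are unaffected regardless of the lie.
#'
#' @param y Current mean vector.
#' @param Sigma Current covariance (as in [covariancePosterior()]).
#' @param pickIndex Index of the conditioned candidate.
#' @param yLie The imagined observation.
#' @return The posterior mean over the remaining candidates.
#' @export
meanPosterior <- function(y, Sigma, pickIndex, yLie) {
  s2 <- Sigma[pickIndex, pickIndex]
  if (s2 <= 0) stop("pick variance must be positive (jitter missing?)")
  v <- Sigma[-pickIndex, pickIndex]
  y[-pickIndex] + v * (yLie - y[pickIndex]) / s2
}

#' Constant-liar batch selection
#'
#' Greedy batch construction that discourages redundant picks: after each
#' pick the predictive distribution is conditioned on a pessimistic
#' imagined outcome (the "lie" — the minimum of the initial consensus), so
#' candidates correlated with what was already picked are down-weighted in
#' later picks. Before the loop, `alpha * median(diag(Sigma))` is added to
#' the covariance diagonal once as observation noise: a small `alpha`
#' makes the lie confident (aggressive exploration), a large `alpha`
#' drowns it out and recovers plain top-N selection.
#'
#' When the covariance carries no signal at all (an all-zero diagonal) the
#' method falls back to [topNSelect()] with a warning.
#'
#' @param pred A [PredictionEnsemble-class].
#' @param batchSize Number of picks (default 16).
#' @param alpha Positive observation-noise multiplier (the benchmark
#'   schedule uses 6 in round 2 and 100 — near-pure exploitation — later).
#' @param ucbBeta Optional upper-confidence-bound coefficient on the
#'   posterior standard deviation in the greedy pick; 0 (default) picks
#'   the posterior-mean maximiser.
#' @return A [Batch-class]; `selectionTrace` records each pick's posterior
#'   mean at pick time.
#' @export
constantLiarSelect <- function(pred, batchSize = 16L, alpha = 6,
                               ucbBeta = 0) {
  stopifnot(alpha > 0)
  ids <- pred@candidateIds
  n <- length(ids)
  if (batchSize > n) {
    warning("batchSize exceeds pool; returning the whole pool")
    batchSize <- n
  }
  Sigma <- pred@covariance
  if (all(diag(Sigma) == 0)) {
    warning("covariance diagonal is all zero; falling back to top-N")
    return(topNSelect(pred, batchSize))
  }
  jitter <- alpha * stats::median(diag(Sigma))
  Sigma <- Sigma + diag(jitter, n)
  y <- pred@consensus
  yLie <- min(pred@consensus)
  sel <- character(0)
  trace <- numeric(0)
  for (step in seq_len(batchSize)) {
    crit <- if (ucbBeta > 0) y + ucbBeta * sqrt(pmax(diag(Sigma), 0)) else y
    pick <- which.max(crit)  # first maximum: ties break by candidate order
    sel <- c(sel, ids[pick])
    trace <- c(trace, y[pick])
    if (step == batchSize) break
    yNew <- meanPosterior(y, Sigma, pick, yLie)
    Sigma <- covariancePosterior(Sigma, pick)
    y <- yNew
    ids <- ids[-pick]
  }
  methods::new("Batch", selectedIds = sel, selectionTrace = trace)
}

#' Random batch selection
#'
#' Uniform sampling without replacement — the traditional directed
#' evolution baseline.
#'
#' @param pool Character vector of candidate ids.
#' @param batchSize Number of picks.
#' @param seed Integer seed.
#' @return A [Batch-class] (`selectionTrace` is NA).
#' @export
randomSelect <- function(pool, batchSize = 16L, seed = 1L) {
  if (batchSize > length(pool)) {
    warning("batchSize exceeds pool; returning the whole pool")
    batchSize <- length(pool)
  }
  sel <- withSeed(seed, sample(pool, batchSize))
  methods::new("Batch", selectedIds = sel,
               selectionTrace = rep(NA_real_, batchSize))
}

#' @rdname accessors
setMethod("selectedIds", "Batch", function(x) x@selectedIds)
#' @rdname accessors
setMethod("selectionTrace", "Batch", function(x) x@selectionTrace)

setMethod("show", "Batch", function(object) {
  cat("Batch of ", length(object@selectedIds), ": ",
      paste(utils::head(object@selectedIds, 8L), collapse = ", "),
      if (length(object@selectedIds) > 8L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "DiversityReport", function(object) {
  cat("DiversityReport: ", object@uniqueLoci, " unique loci, ",
      object@newLoci, " new\n", sep = "")
})

#' Batch diversity report
#'
#' Counts the distinct mutated positions (loci) in a batch and how many of
#' them were never mutated in any earlier batch of the campaign.
#'
#' @param batch A [Batch-class] or character vector of mutation strings.
#' @param history Previous batches: a list of [Batch-class]/character
#'   vectors, or a single character vector of mutation strings.
#' @return A [DiversityReport-class].
#' @export
diversityReport <- function(batch, history = character(0)) {
  asMut <- function(x) if (methods::is(x, "Batch")) x@selectedIds else x
  loci <- unique(unlist(mutatedPositions(asMut(batch)), use.names = FALSE))
  prev <- unlist(lapply(if (is.list(history)) history else list(history),
                        asMut), use.names = FALSE)
  prevLoci <- if (length(prev))
    unique(unlist(mutatedPositions(prev), use.names = FALSE)) else integer(0)
  methods::new("DiversityReport",
               uniqueLoci = length(loci),
               newLoci = length(setdiff(loci, prevLoci)))
}
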