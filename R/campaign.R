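# The iterative design-simulate loop: candidate-pool expansion, the four
# selection strategies, campaign metrics, bootstrapped benchmarks and the
# paired Wilcoxon comparison.

#' Build a campaign configuration
#'
#' Defaults encode the benchmark protocol: 3 rounds of 16 mutants over the
#' accessible half of a landscape; the `folde` strategy selects round 1 by
#' zero-shot naturalness, later rounds by a warm-started Bradley-Terry
#' ensemble with constant-liar batches (alpha 6 in round 2, 100 — almost
#' pure exploitation — afterwards).
#'
#' @param rounds,batchSize Campaign shape (defaults 3 x 16).
#' @param strategy One of `"folde"`, `"random"`, `"zero_shot"`,
#'   `"random_forest"` (the last representing the common
#'   embeddings-plus-random-forest few-shot workflow).
#' @param alphaSchedule Named numeric, alpha per round (names `"2"`,
#'   `"3"`, ...). Default: 6 in round 2, 100 in every later round.
#' @param warmStart Warm-start the ensemble on naturalness (default TRUE).
#' @param hitRule What counts as a "high-performing" mutant when expanding
#'   the candidate pool: `"above_wt"` (measured activity strictly above
#'   the wild type's 0), `"top_quartile"` of measured, or `"top_k"`.
#' @param hitK k for `hitRule = "top_k"`.
#' @param holdoutFraction Held-out fraction per replicate (default 0.5).
#' @param seed Campaign seed; every stochastic stage derives from it.
#' @param trainCfg A [TrainConfig-class] for the ensemble.
#' @param nMembers Ensemble size (default 5).
#' @param ucbBeta Upper-confidence-bound coefficient in the greedy
#'   constant-liar pick (default 0 = posterior mean).
#' @param heldoutDiagnosticMax Cap on held-out mutants scored for the
#'   Spearman diagnostic (default 2000, seeded subsample).
#' @param metricScope Percentile reference for the metrics:
#'   `"accessible"` (default; selection is restricted to that half) or
#'   `"full"`.
#' @return A [CampaignConfig-class].
#' @export
campaignConfig <- function(rounds = 3L, batchSize = 16L,
                           strategy = "folde", alphaSchedule = NULL,
                           warmStart = TRUE, hitRule = "above_wt",
                           hitK = 16L, holdoutFraction = 0.5, seed = 1L,
                           trainCfg = trainConfig(), nMembers = 5L,
                           ucbBeta = 0, heldoutDiagnosticMax = 2000L,
                           metricScope = "accessible") {
  rounds <- as.integer(rounds)
  if (is.null(alphaSchedule) && rounds >= 2L) {
    alphaSchedule <- stats::setNames(c(6, rep(100, max(0L, rounds - 2L))),
                                     as.character(2:rounds))
  }
  methods::new("CampaignConfig", values = list(
    rounds = rounds, batchSize = as.integer(batchSize), strategy = strategy,
    alphaSchedule = alphaSchedule, warmStart = isTRUE(warmStart),
    hitRule = hitRule, hitK = as.integer(hitK),
    holdoutFraction = holdoutFraction, seed = as.integer(seed),
    trainCfg = trainCfg, nMembers = as.integer(nMembers),
    ucbBeta = ucbBeta,
    heldoutDiagnosticMax = as.integer(heldoutDiagnosticMax),
    metricScope = metricScope))
}

#' Configuration values of a CampaignConfig
#'
#' @param config A [CampaignConfig-class].
#' @return Its named list of settings.
#' @export
campaignConfigValues <- function(config) config@values

setMethod("show", "CampaignConfig", function(object) {
  v <- object@values
  cat("CampaignConfig: ", v$rounds, " rounds x ", v$batchSize,
      " (strategy ", v$strategy, ", seed ", v$seed, ")\n", sep = "")
})

# Canonical key of a mutation set: tokens sorted by position.
.mutKey <- function(strings) {
  vapply(parseMutations(strings), function(df) {
    o <- order(df$position)
    paste0(df$wt[o], df$position[o], df$mut[o], collapse = ":")
  }, character(1))
}

#' Expand the candidate pool from measured hits
#'
#' The search space grows progressively: a candidate qualifies if it is a
#' single mutant (an extension of the wild type) or if its mutation set
#' extends some measured high-performing mutant by exactly one mutation.
#' Previously measured mutants are excluded, and everything is restricted
#' to the accessible half.
#'
#' @param measured Named numeric vector of measured activities.
#' @param landscape The [Landscape-class].
#' @param accessible Character vector of accessible ids.
#' @param hitRule,hitK See [campaignConfig()].
#' @return Character vector of candidate ids; error if empty.
#' @export
expandPool <- function(measured, landscape, accessible,
                       hitRule = "above_wt", hitK = 16L) {
  if (length(measured) == 0L) stop("need at least one measured round")
  hits <- switch(hitRule,
    above_wt = names(measured)[measured > 0],
    top_quartile = names(measured)[measured >=
      stats::quantile(measured, 0.75, type = 7)],
    top_k = names(measured)[order(-measured)[seq_len(min(hitK,
      length(measured)))]],
    stop("unknown hitRule: ", hitRule))
  rec <- landscape@records
  rec <- rec[rec$id %in% setdiff(accessible, names(measured)), ,
             drop = FALSE]
  pool <- rec$id[rec$nMutations == 1L]
  multi <- rec[rec$nMutations > 1L, , drop = FALSE]
  if (nrow(multi) > 0L && length(hits) > 0L) {
    hitKeys <- .mutKey(landscape@records$mutant[
      match(hits, landscape@records$id)])
    ok <- vapply(parseMutations(multi$mutant), function(df) {
      o <- order(df$position)
      df <- df[o, , drop = FALSE]
      toks <- paste0(df$wt, df$position, df$mut)
      any(vapply(seq_along(toks), function(k)
        paste(toks[-k], collapse = ":") %in% hitKeys, logical(1)))
    }, logical(1))
    pool <- c(pool, multi$id[ok])
  }
  if (length(pool) == 0L)
    stop("candidate pool is empty: campaign cannot continue")
  pool
}

#' Campaign metrics from the selected mutants
#'
#' Top-10% and top-1% thresholds are computed on the ground-truth
#' activities of the reference set (by default the accessible half, since
#' selection is restricted to it) with linear-interpolation percentiles,
#' and selections are counted at or above them.
#'
#' @param selectedByRound List of per-round id vectors (or one vector).
#' @param landscape The [Landscape-class].
#' @param referenceIds Ids defining the percentile reference set.
#' @return A [CampaignMetrics-class].
#' @export
computeMetrics <- function(selectedByRound, landscape, referenceIds) {
  if (!is.list(selectedByRound)) selectedByRound <- list(selectedByRound)
  ref <- activities(landscape, referenceIds)
  t90 <- stats::quantile(ref, 0.90, type = 7, names = FALSE)
  t99 <- stats::quantile(ref, 0.99, type = 7, names = FALSE)
  perRound <- vapply(selectedByRound, function(ids)
    sum(activities(landscape, ids) >= t90), integer(1))
  anyTop1 <- any(vapply(selectedByRound, function(ids)
    any(activities(landscape, ids) >= t99), logical(1)))
  methods::new("CampaignMetrics",
               cumulativeTop10Hits = as.integer(sum(perRound)),
               foundTop1 = anyTop1, perRoundHits = perRound)
}

setMethod("show", "CampaignMetrics", function(object) {
  cat("CampaignMetrics: ", object@cumulativeTop10Hits,
      " top-10% hits (per round: ",
      paste(object@perRoundHits, collapse = ", "), "); top-1% found: ",
      object@foundTop1, "\n", sep = "")
})

# Embeddings of a set of record ids (mutation strings applied to the wild
# type), rownames = ids.
.embedIds <- function(embedder, wt, ids, mutants = ids) {
  seqs <- vapply(mutants, function(m) applyMutations(wt, m), character(1))
  E <- embedSequences(embedder, seqs)
  rownames(E) <- ids
  E
}

#' Run one simulated optimization campaign
#'
#' Simulates an iterative low-N campaign on a landscape oracle: each round
#' selects a batch from the accessible half, looks its activities up, and
#' (for learning strategies) retrains before the next round. Round 1 is
#' zero-shot naturalness for `folde`/`zero_shot` and random for
#' `random`/`random_forest`; later rounds follow the strategy. The
#' held-out half is never selected or trained on — it only feeds the
#' Spearman ranking diagnostic.
#'
#' @param landscape A [Landscape-class].
#' @param embedder An [Embedder-class] whose wild type matches.
#' @param config A [CampaignConfig-class].
#' @param split Optional [HoldoutSplit-class]; by default drawn from the
#'   campaign seed.
#' @return List with `rounds` (list of [RoundResult-class]), `metrics`
#'   (a [CampaignMetrics-class]) and `split`.
#' @export
runCampaign <- function(landscape, embedder, config, split = NULL) {
  v <- config@values
  wt <- wildType(landscape)
  if (!identical(wt, wildType(embedder)))
    stop("embedder and landscape wild types differ")
  if (is.null(split))
    split <- holdoutSplit(landscape, v$holdoutFraction,
                          deriveSeed(v$seed, 1L))
  accessible <- split@accessibleIds
  table <- naturalnessTable(logProbMatrix(embedder))
  rec <- landscape@records
  accSingles <- rec$id[rec$id %in% accessible & rec$nMutations == 1L]

  measured <- numeric(0)
  roundResults <- vector("list", v$rounds)
  selectedByRound <- vector("list", v$rounds)
  batchHistory <- list()

  for (r in seq_len(v$rounds)) {
    pool <- if (r == 1L) accSingles
            else expandPool(measured, landscape, accessible,
                            v$hitRule, v$hitK)
    heldSp <- NA_real_
    if (r == 1L) {
      batch <- switch(v$strategy,
        folde = , zero_shot = zeroShotSelect(
          table, v$batchSize,
          exclude = setdiff(table@entries$id, pool)),
        random = , random_forest = randomSelect(
          pool, v$batchSize, deriveSeed(v$seed, 10L + r)))
    } else if (v$strategy == "zero_shot") {
      batch <- zeroShotSelect(table, v$batchSize,
                              exclude = setdiff(table@entries$id, pool))
    } else if (v$strategy == "random") {
      batch <- randomSelect(pool, v$batchSize, deriveSeed(v$seed, 10L + r))
    } else {
      # learning strategies: embed what this round needs
      needIds <- unique(c(names(measured), pool))
      if (v$strategy == "folde" && v$warmStart)
        needIds <- unique(c(needIds, table@entries$id[
          table@entries$id %in% rec$id]))
      heldIds <- split@heldOutIds
      if (length(heldIds) > v$heldoutDiagnosticMax)
        heldIds <- withSeed(deriveSeed(v$seed, 90L + r),
                            sample(heldIds, v$heldoutDiagnosticMax))
      emb <- .embedIds(embedder, wt, unique(c(needIds, heldIds)))
      if (v$strategy == "folde") {
        warmTable <- if (v$warmStart) table else NULL
        ens <- trainRankerEnsemble(measured, emb, v$trainCfg,
                                   table = warmTable,
                                   nMembers = v$nMembers,
                                   baseSeed = deriveSeed(v$seed, 50L + r))
        pred <- predictEnsemble(ens, emb[pool, , drop = FALSE])
        alpha <- v$alphaSchedule[[as.character(r)]]
        batch <- constantLiarSelect(pred, v$batchSize, alpha, v$ucbBeta)
        heldPred <- predictEnsemble(ens, emb[heldIds, , drop = FALSE])
        heldSp <- spearmanCor(heldPred@consensus,
                              activities(landscape, heldIds))
      } else {  # random_forest baseline
        rf <- withSeed(deriveSeed(v$seed, 70L + r),
          randomForest::randomForest(
            x = emb[names(measured), , drop = FALSE], y = measured))
        pr <- stats::predict(rf, emb[pool, , drop = FALSE])
        ord <- order(-pr)[seq_len(min(v$batchSize, length(pool)))]
        batch <- methods::new("Batch", selectedIds = pool[ord],
                              selectionTrace = as.numeric(pr[ord]))
        heldSp <- spearmanCor(
          as.numeric(stats::predict(rf, emb[heldIds, , drop = FALSE])),
          activities(landscape, heldIds))
      }
    }
    sel <- batch@selectedIds
    stopifnot(all(sel %in% accessible), !any(sel %in% names(measured)))
    meas <- activities(landscape, sel)
    div <- diversityReport(rec$mutant[match(sel, rec$id)],
                           lapply(batchHistory, function(ids)
                             rec$mutant[match(ids, rec$id)]))
    roundResults[[r]] <- methods::new("RoundResult",
      roundIndex = r,
      selected = batch, measurements = meas,
      heldoutSpearman = heldSp, diversity = div)
    selectedByRound[[r]] <- sel
    batchHistory <- c(batchHistory, list(sel))
    measured <- c(measured, meas)
  }
  refIds <- if (v$metricScope == "full") rec$id else accessible
  list(rounds = roundResults,
       metrics = computeMetrics(selectedByRound, landscape, refIds),
       split = split)
}

setMethod("show", "RoundResult", function(object) {
  cat("RoundResult ", object@roundIndex, ": ",
      length(object@selected@selectedIds), " selected, best activity ",
      format(max(object@measurements), digits = 4),
      if (!is.na(object@heldoutSpearman))
        paste0(", held-out Spearman ",
               format(object@heldoutSpearman, digits = 3)) else "",
      "\n", sep = "")
})

#' Bootstrapped benchmark over replicated campaigns
#'
#' Each replicate draws a fresh 50% holdout and campaign seed; every
#' strategy runs on the same split and seed within a replicate (paired),
#' which is what the signed-rank comparison presupposes. The probability
#' of finding a top-1% mutant is estimated as the fraction of replicates
#' whose campaign found one.
#'
#' @param landscape A [Landscape-class].
#' @param embedder An [Embedder-class].
#' @param configs Named list of [CampaignConfig-class], one per strategy.
#' @param nReplicates Number of replicates (>= 2).
#' @param seed Master seed.
#' @return `data.frame` with one row per (strategy, replicate):
#'   `cumulativeTop10Hits`, `foundTop1`, per-round hits and the round-2
#'   held-out Spearman diagnostic.
#' @export
bootstrapBenchmark <- function(landscape, embedder, configs,
                               nReplicates = 20L, seed = 1L) {
  stopifnot(nReplicates >= 2L, length(names(configs)) == length(configs))
  out <- list()
  for (i in seq_len(nReplicates)) {
    repSeed <- deriveSeed(seed, 1000L + i)
    split <- holdoutSplit(landscape,
                          configs[[1]]@values$holdoutFraction, repSeed)
    for (nm in names(configs)) {
      cfg <- configs[[nm]]
      cfg@values$seed <- repSeed
      res <- runCampaign(landscape, embedder, cfg, split = split)
      m <- res$metrics
      sp2 <- if (cfg@values$rounds >= 2L)
        res$rounds[[2]]@heldoutSpearman else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        strategy = nm, replicate = i,
        cumulativeTop10Hits = m@cumulativeTop10Hits,
        foundTop1 = m@foundTop1,
        round1Hits = m@perRoundHits[1],
        round2Spearman = sp2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Paired one-sided Wilcoxon test on log-transformed counts
#'
#' Tests whether workflow A discovers more top performers than workflow B
#' across paired simulations: a one-sided Wilcoxon signed-rank test on
#' `log(countsA) - log(countsB)` (alternative: A greater). When any count
#' is zero, both sides are shifted by +1 before the log (logged). Exact
#' p-values for n <= 25 nonzero differences without ties, normal
#' approximation with continuity correction otherwise; all-zero
#' differences return p = 1 with the degenerate flag set.
#'
#' @param countsA,countsB Paired non-negative counts.
#' @return List with `p`, `statistic` (the signed-rank statistic), `n`
#'   (nonzero differences), `shifted`, `degenerate`.
#' @export
wilcoxonLogRatio <- function(countsA, countsB) {
  stopifnot(length(countsA) == length(countsB), length(countsA) >= 1L)
  shift <- any(c(countsA, countsB) == 0)
  if (shift) {
    foldeLog("zero counts present: applying +1 shift before log")
    countsA <- countsA + 1
    countsB <- countsB + 1
  }
  d <- log(countsA) - log(countsB)
  nz <- d[d != 0]
  if (length(nz) == 0L)
    return(list(p = 1, statistic = NA_real_, n = 0L, shifted = shift,
                degenerate = TRUE))
  exact <- length(nz) <= 25L && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(stats::wilcox.test(
    nz, alternative = "greater", exact = exact, correct = TRUE))
  list(p = unname(wt$p.value), statistic = unname(wt$statistic),
       n = length(nz), shifted = shift, degenerate = FALSE)
}
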