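# Naturalness scoring (wild-type-marginal log-likelihood ratio) and
# zero-shot batch selection.

#' Naturalness of a mutant
#'
#' The log-likelihood ratio of mutant to wild-type amino acids under the
#' model's per-position distributions, summed over the mutated positions:
#' `sum_i [log P(x'_i | x) - log P(x_i | x)]`. Separate mutations are
#' treated independently, so a multi-mutant's score is the sum of its
#' single-mutant scores; the empty mutation set (the wild type) scores 0.
#'
#' @param mutations A mutation `data.frame` (see [parseMutationString()]),
#'   a mutation string, or `NULL` for the wild type.
#' @param lp A [LogProbMatrix-class] conditioned on the wild type.
#' @return A single naturalness value (unitless log-ratio).
#' @export
naturalnessScore <- function(mutations, lp) {
  if (is.character(mutations)) mutations <- parseMutationString(mutations)
  if (is.null(mutations) || nrow(mutations) == 0L) return(0)
  v <- lp@values
  if (any(mutations$position > nrow(v)))
    stop("mutation position out of range of the log-probability matrix")
  wtChars <- strsplit(lp@wildType, "")[[1]]
  if (any(wtChars[mutations$position] != mutations$wt))
    stop("mutation wt letter disagrees with the matrix wild type")
  mutIdx <- match(mutations$mut, AA_ALPHABET)
  wtIdx <- match(wtChars[mutations$position], AA_ALPHABET)
  sum(v[cbind(mutations$position, mutIdx)] -
        v[cbind(mutations$position, wtIdx)])
}

#' Naturalness of all single mutants
#'
#' Tabulates the naturalness of every possible single mutant (L x 19
#' entries): the ranking substrate of zero-shot selection and the target
#' set of the warm-start.
#'
#' @param lp A [LogProbMatrix-class].
#' @return A [NaturalnessTable-class].
#' @export
naturalnessTable <- function(lp) {
  v <- lp@values
  L <- nrow(v)
  wtChars <- strsplit(lp@wildType, "")[[1]]
  wtIdx <- match(wtChars, AA_ALPHABET)
  nat <- v - v[cbind(seq_len(L), wtIdx)]
  entries <- data.frame(
    position = rep(seq_len(L), each = 20L),
    mutAa = rep(AA_ALPHABET, times = L),
    naturalness = as.numeric(t(nat)),
    stringsAsFactors = FALSE)
  entries <- entries[entries$mutAa != wtChars[entries$position], ]
  entries$id <- paste0(wtChars[entries$position], entries$position,
                       entries$mutAa)
  rownames(entries) <- NULL
  methods::new("NaturalnessTable",
               entries = entries[c("id", "position", "mutAa", "naturalness")],
               wildType = lp@wildType)
}

#' Naturalness entries as a data.frame
#'
#' @param table A [NaturalnessTable-class].
#' @return Its `entries` data.frame.
#' @export
naturalnessEntries <- function(table) table@entries

setMethod("show", "NaturalnessTable", function(object) {
  cat("NaturalnessTable: ", nrow(object@entries), " single mutants of a ",
      "length-", nchar(object@wildType), " wild type\n", sep = "")
})

#' Zero-shot batch selection by naturalness
#'
#' Greedy descending-naturalness selection of a batch of single mutants,
#' optionally capping the number of selections per locus: once a position
#' already holds `maxPerLocus` picks in the batch, further candidates at
#' that position are skipped and the next-best other-locus candidate is
#' taken. Ties in naturalness are broken lexicographically by
#' (position, mutant letter), so selection is deterministic and seed-free.
#'
#' @param table A [NaturalnessTable-class].
#' @param batchSize Number of mutants to select (default 16).
#' @param maxPerLocus Optional cap on picks per position (`NULL` = no cap;
#'   the practical design default is 3, simulations run uncapped).
#' @param exclude Ids never to return (e.g. previous batches).
#' @return A [Batch-class]; `selectionTrace` holds the naturalness of each
#'   pick.
#' @export
zeroShotSelect <- function(table, batchSize = 16L, maxPerLocus = NULL,
                           exclude = character(0)) {
  e <- table@entries
  e <- e[!(e$id %in% exclude), , drop = FALSE]
  e <- e[order(-e$naturalness, e$position, e$mutAa), , drop = FALSE]
  sel <- integer(0)
  perLocus <- integer(0)
  for (i in seq_len(nrow(e))) {
    if (length(sel) >= batchSize) break
    p <- as.character(e$position[i])
    used <- if (p %in% names(perLocus)) perLocus[[p]] else 0L
    if (!is.null(maxPerLocus) && used >= maxPerLocus) next
    sel <- c(sel, i)
    perLocus[p] <- used + 1L
  }
  if (length(sel) < batchSize)
    stop("insufficient eligible candidates: needed ", batchSize,
         ", found ", length(sel))
  methods::new("Batch", selectedIds = e$id[sel],
               selectionTrace = e$naturalness[sel])
}
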