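# Landscape construction, DMS file I/O, holdout splitting and the
# engineering-difficulty statistic.

#' Construct a Landscape
#'
#' @param wildType Amino-acid string.
#' @param mutants Character vector of mutation strings (one per record).
#' @param activity Numeric ground-truth activities, same length.
#' @param ids Optional record ids; default the mutation strings themselves.
#' @param name Label.
#' @return A validated [Landscape-class].
#' @examples
#' Landscape("ACDEF", c("A1G", "C2T"), c(0.1, -0.2))
#' @export
Landscape <- function(wildType, mutants, activity, ids = mutants,
                      name = "landscape") {
  rec <- data.frame(id = as.character(ids), mutant = as.character(mutants),
                    activity = as.numeric(activity),
                    stringsAsFactors = FALSE)
  rec$nMutations <- lengths(strsplit(rec$mutant, ":", fixed = TRUE))
  methods::new("Landscape", wildType = wildType, records = rec, name = name)
}

#' @rdname accessors
setMethod("wildType", "Landscape", function(x) x@wildType)
#' @rdname accessors
setMethod("records", "Landscape", function(x) x@records)
#' @rdname accessors
setMethod("landscapeName", "Landscape", function(x) x@name)
#' @rdname accessors
setMethod("wildType", "LogProbMatrix", function(x) x@wildType)
#' @rdname accessors
setMethod("wildType", "NaturalnessTable", function(x) x@wildType)
#' @rdname accessors
setMethod("wildType", "SyntheticOracle", function(x) x@wildType)
#' @rdname accessors
setMethod("accessibleIds", "HoldoutSplit", function(x) x@accessibleIds)
#' @rdname accessors
setMethod("heldOutIds", "HoldoutSplit", function(x) x@heldOutIds)

setMethod("show", "Landscape", function(object) {
  rec <- object@records
  cat("Landscape '", object@name, "': wild type of length ",
      nchar(object@wildType), ", ", nrow(rec), " mutants (",
      sum(rec$nMutations == 1L), " single, ",
      sum(rec$nMutations > 1L), " multi)\n", sep = "")
})

setMethod("show", "HoldoutSplit", function(object) {
  cat("HoldoutSplit: ", length(object@accessibleIds), " accessible / ",
      length(object@heldOutIds), " held out (seed ", object@seed, ")\n",
      sep = "")
})

#' Read a wild-type sequence from a FASTA file
#'
#' @param path FASTA file with at least one record; the first is used.
#' @return The sequence as a plain uppercase string.
#' @export
readWildTypeFasta <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  toupper(as.character(seqs[[1]]))
}

#' Read a ProteinGym-style DMS table as a Landscape
#'
#' Reads a CSV with a mutation-string column and a numeric score column.
#' Rows with missing scores are skipped with a warning; the counts of rows
#' read and skipped are emitted to the log. The wild-type sequence is
#' resolved with precedence: explicit FASTA sidecar, then the `wildType`
#' argument, then reconstruction from the wild-type letters of the mutation
#' strings (an error if any position of the sequence is never mutated, since
#' its letter would be unknown).
#'
#' @param path CSV file path.
#' @param mutantColumn,scoreColumn Column names (ProteinGym defaults).
#' @param fasta Optional FASTA sidecar with the wild-type sequence.
#' @param wildType Optional wild-type string (used if no `fasta`).
#' @param name Landscape label; default the file name.
#' @return A [Landscape-class].
#' @export
readDmsCsv <- function(path, mutantColumn = "mutant",
                       scoreColumn = "DMS_score", fasta = NULL,
                       wildType = NULL, name = basename(path)) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty DMS table: ", path)
  if (!all(c(mutantColumn, scoreColumn) %in% names(df)))
    stop("missing column(s): ",
         paste(setdiff(c(mutantColumn, scoreColumn), names(df)),
               collapse = ", "))
  nRead <- nrow(df)
  score <- suppressWarnings(as.numeric(df[[scoreColumn]]))
  keep <- !is.na(score)
  nSkipped <- sum(!keep)
  if (nSkipped > 0L)
    warning(nSkipped, " row(s) with missing scores skipped")
  df <- df[keep, , drop = FALSE]
  score <- score[keep]
  muts <- parseMutations(df[[mutantColumn]])
  if (!is.null(fasta)) {
    wt <- readWildTypeFasta(fasta)
  } else if (!is.null(wildType)) {
    wt <- toupper(wildType)
  } else {
    pos <- unlist(lapply(muts, `[[`, "position"), use.names = FALSE)
    aa <- unlist(lapply(muts, `[[`, "wt"), use.names = FALSE)
    L <- max(pos)
    wtChars <- rep(NA_character_, L)
    first <- !duplicated(pos)
    wtChars[pos[first]] <- aa[first]
    clash <- tapply(aa, pos, function(x) length(unique(x)) > 1L)
    if (any(clash))
      stop("inconsistent wild-type letters at position(s): ",
           paste(names(clash)[clash], collapse = ", "))
    if (anyNA(wtChars))
      stop("cannot reconstruct wild type: no mutation at position(s) ",
           paste(which(is.na(wtChars)), collapse = ", "),
           "; supply `fasta` or `wildType`")
    wt <- paste(wtChars, collapse = "")
  }
  foldeLog("read ", nRead, " rows from ", path, "; kept ", nrow(df),
           ", skipped ", nSkipped)
  Landscape(wildType = wt, mutants = df[[mutantColumn]], activity = score,
            name = name)
}

#' Split a landscape into accessible and held-out halves
#'
#' Each simulation replicate holds out a fraction of the mutants: selection
#' and training see only the accessible half, the held-out half serves the
#' ranking diagnostic and enables bootstrapping over replicates.
#'
#' @param landscape A [Landscape-class].
#' @param fraction Held-out fraction in (0, 1); default 0.5.
#' @param seed Integer seed; the split is deterministic given it.
#' @return A [HoldoutSplit-class] with `round(fraction * N)` held-out ids.
#' @export
holdoutSplit <- function(landscape, fraction = 0.5, seed = 1L) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)")
  ids <- landscape@records$id
  if (length(ids) < 2L) stop("need at least 2 records to split")
  nHold <- round(fraction * length(ids))
  held <- withSeed(seed, sample(ids, nHold))
  methods::new("HoldoutSplit",
               accessibleIds = setdiff(ids, held),
               heldOutIds = held, seed = as.integer(seed))
}

#' Engineering difficulty of a landscape
#'
#' The min-max-scaled activity of the 99.375th-percentile mutant,
#' `(A_99.375% - A_min) / (A_max - A_min)`: the relative activity a
#' campaign of 10 random batches of 16 would reach in expectation at its
#' best pick. Values near 1 mean the top of the landscape is far above
#' what random sampling attains, i.e. a hard target. Percentiles use
#' linear interpolation between order statistics (`quantile` type 7),
#' the same convention as the campaign metrics.
#'
#' @param landscape A [Landscape-class] with at least two distinct
#'   activity values.
#' @return A number in `[0, 1]`.
#' @export
difficulty <- function(landscape) {
  a <- landscape@records$activity
  if (length(unique(a)) < 2L)
    stop("difficulty undefined: activities have zero range")
  q <- stats::quantile(a, 0.99375, type = 7, names = FALSE)
  (q - min(a)) / (max(a) - min(a))
}
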