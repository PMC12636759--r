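# Mutation notation (ProteinGym dialect): colon-separated tokens of the
# form <wt letter><1-based position><mutant letter>, e.g. "A24G:T56C".
# Mutations are represented as a data.frame with columns wt, position, mut.

.MUT_TOKEN_RE <- "^([A-Za-z])([0-9]+)([A-Za-z])$"

#' Parse a mutation string
#'
#' Parses a colon-separated ProteinGym-style mutation string (`"A24G"`,
#' `"A24G:T56C"`) into a mutation table. Positions are 1-based. Tokens must
#' use canonical amino-acid letters, the wild-type letter must differ from
#' the substituted letter, and positions must be pairwise distinct.
#'
#' @param s A single non-empty mutation string.
#' @return A `data.frame` with one row per mutation and columns `wt`
#'   (wild-type letter), `position` (integer, 1-based), `mut` (mutant
#'   letter), in the order the tokens appear.
#' @examples
#' parseMutationString("A24G:T56C")
#' @seealso [formatMutations()], [applyMutations()]
#' @export
parseMutationString <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
    stop("mutation string must be a single non-empty string")
  tokens <- strsplit(s, ":", fixed = TRUE)[[1]]
  m <- regmatches(tokens, regexec(.MUT_TOKEN_RE, tokens))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad))
    stop("malformed mutation token: '", tokens[bad][1], "'")
  wt <- toupper(vapply(m, `[`, character(1), 2L))
  pos <- as.integer(vapply(m, `[`, character(1), 3L))
  mut <- toupper(vapply(m, `[`, character(1), 4L))
  nonCanon <- !(wt %in% AA_ALPHABET) | !(mut %in% AA_ALPHABET)
  if (any(nonCanon))
    stop("non-canonical amino-acid letter in token: '", tokens[nonCanon][1], "'")
  if (any(wt == mut))
    stop("wild-type equals mutant letter in token: '", tokens[wt == mut][1], "'")
  if (anyDuplicated(pos))
    stop("duplicate position in mutation string: '", s, "'")
  if (any(pos < 1L))
    stop("positions must be >= 1 in: '", s, "'")
  data.frame(wt = wt, position = pos, mut = mut, stringsAsFactors = FALSE)
}

#' Format a mutation table back into a string
#'
#' Inverse of [parseMutationString()]; `parse` then `format` round-trips any
#' well-formed mutation string.
#'
#' @param mutations A mutation `data.frame` (columns `wt`, `position`, `mut`).
#' @return A single mutation string, tokens in row order.
#' @export
formatMutations <- function(mutations) {
  if (nrow(mutations) == 0L) return("")
  paste0(mutations$wt, mutations$position, mutations$mut, collapse = ":")
}

# Vectorised parser used on whole record tables; no per-token validation
# beyond the regex (callers validate via parseMutationString where needed).
# Returns a list of data.frames aligned with `strings`.
parseMutations <- function(strings) {
  lapply(strings, function(s) {
    tokens <- strsplit(s, ":", fixed = TRUE)[[1]]
    m <- regmatches(tokens, regexec(.MUT_TOKEN_RE, tokens))
    if (any(vapply(m, length, integer(1)) != 4L))
      stop("malformed mutation token in '", s, "'")
    data.frame(wt = vapply(m, `[`, character(1), 2L),
               position = as.integer(vapply(m, `[`, character(1), 3L)),
               mut = vapply(m, `[`, character(1), 4L),
               stringsAsFactors = FALSE)
  })
}

# Distinct mutated positions per mutation string, vectorised.
mutatedPositions <- function(strings) {
  lapply(parseMutations(strings), function(df) unique(df$position))
}

#' Apply mutations to a wild-type sequence
#'
#' @param wildType Amino-acid string.
#' @param mutations A mutation `data.frame` from [parseMutationString()], or
#'   a mutation string, or `NULL`/empty for the identity.
#' @return The mutant sequence; differs from `wildType` exactly at the
#'   mutated positions. Errors if any mutation's wild-type letter does not
#'   match the sequence at its position.
#' @examples
#' applyMutations("ACD", "C2G")
#' @export
applyMutations <- function(wildType, mutations) {
  if (is.character(mutations))
    mutations <- parseMutationString(mutations)
  chars <- strsplit(wildType, "")[[1]]
  if (is.null(mutations) || nrow(mutations) == 0L) return(wildType)
  if (any(mutations$position > length(chars)))
    stop("mutation position ", max(mutations$position),
         " beyond sequence length ", length(chars))
  mismatch <- chars[mutations$position] != mutations$wt
  if (any(mismatch)) {
    i <- which(mismatch)[1]
    stop("wild-type mismatch at position ", mutations$position[i],
         ": sequence holds ", chars[mutations$position[i]],
         ", mutation expects ", mutations$wt[i])
  }
  chars[mutations$position] <- mutations$mut
  paste(chars, collapse = "")
}
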