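# Shared internal helpers.

# Structured log line; suppressible via suppressMessages().
foldeLog <- function(...) {
  message("[folde] ", ...)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic sub-seed derivation that stays below 2^31 (exact in double
# arithmetic).
deriveSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) %% 65521 * 1103515245 + salt) %% 2147483647)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# log(1 + exp(x)) without overflow.
softplus <- function(x) {
  ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
}

spearmanCor <- function(x, y) {
  suppressWarnings(stats::cor(x, y, method = "spearman"))
}

# Activities of a landscape as a named numeric vector.
#' Ground-truth activities of a landscape
#'
#' @param landscape A [Landscape-class].
#' @param ids Optional id subset (order preserved).
#' @return Named numeric vector of activities.
#' @export
activities <- function(landscape, ids = NULL) {
  rec <- landscape@records
  a <- stats::setNames(rec$activity, rec$id)
  if (is.null(ids)) a else a[ids]
}
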