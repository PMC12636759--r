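#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics used throughout the package in place of direct
#' slot access: `wildType()` returns the reference amino-acid sequence of an
#' object, `records()` the mutant table of a [Landscape-class],
#' `landscapeName()` its label, `accessibleIds()`/`heldOutIds()` the two
#' halves of a [HoldoutSplit-class], `candidateIds()`, `memberScores()`,
#' `consensus()` and `covarianceMatrix()` the components of a
#' [PredictionEnsemble-class], `selectedIds()` and `selectionTrace()` the
#' contents of a [Batch-class], and `trainPairs()`/`valPairs()` the two
#' halves of a [PairSplit-class].
#'
#' @param x An object of the appropriate class.
#' @return The slot value; see each class page for its type.
#' @name accessors
#' @aliases wildType records landscapeName accessibleIds heldOutIds
#'   candidateIds memberScores consensus covarianceMatrix selectedIds
#'   selectionTrace trainPairs valPairs
NULL

#' @rdname accessors
#' @export
setGeneric("wildType", function(x) standardGeneric("wildType"))

#' @rdname accessors
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("landscapeName", function(x) standardGeneric("landscapeName"))

#' @rdname accessors
#' @export
setGeneric("accessibleIds", function(x) standardGeneric("accessibleIds"))

#' @rdname accessors
#' @export
setGeneric("heldOutIds", function(x) standardGeneric("heldOutIds"))

#' @rdname accessors
#' @export
setGeneric("candidateIds", function(x) standardGeneric("candidateIds"))

#' @rdname accessors
#' @export
setGeneric("memberScores", function(x) standardGeneric("memberScores"))

#' @rdname accessors
#' @export
setGeneric("consensus", function(x) standardGeneric("consensus"))

#' @rdname accessors
#' @export
setGeneric("covarianceMatrix", function(x) standardGeneric("covarianceMatrix"))

#' @rdname accessors
#' @export
setGeneric("selectedIds", function(x) standardGeneric("selectedIds"))

#' @rdname accessors
#' @export
setGeneric("selectionTrace", function(x) standardGeneric("selectionTrace"))

#' @rdname accessors
#' @export
setGeneric("trainPairs", function(x) standardGeneric("trainPairs"))

#' @rdname accessors
#' @export
setGeneric("valPairs", function(x) standardGeneric("valPairs"))

#' Embedder contract
#'
#' An embedder turns amino-acid sequences into fixed-length numeric vectors
#' and supplies per-position amino-acid log-probabilities for its wild-type
#' sequence (the substrate of naturalness scoring). The package ships a
#' deterministic [SyntheticOracle-class]; an adapter around a real protein
#' language model only needs to implement these three generics to drive the
#' whole workflow.
#'
#' @param x An [Embedder-class] object.
#' @param sequences Character vector of amino-acid sequences.
#' @return `embedDim()` the embedding length; `embedSequences()` a numeric
#'   matrix with one row per sequence and `embedDim(x)` columns;
#'   `logProbMatrix()` a [LogProbMatrix-class] for the wild type.
#' @name embedder-contract
#' @aliases embedDim embedSequences logProbMatrix
NULL

#' @rdname embedder-contract
#' @export
setGeneric("embedDim", function(x) standardGeneric("embedDim"))

#' @rdname embedder-contract
#' @export
setGeneric("embedSequences", function(x, sequences)
  standardGeneric("embedSequences"))

#' @rdname embedder-contract
#' @export
setGeneric("logProbMatrix", function(x) standardGeneric("logProbMatrix"))
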