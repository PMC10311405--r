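#' PoreModel: expected mean current level per k-mer
#'
#' Lookup table of the expected mean current level (pA scale; units are
#' irrelevant after normalization) for each of the 4^k k-mers of a nanopore
#' chemistry, as distributed with ONT-style k-mer model files.
#'
#' @slot k k-mer length in bases.
#' @slot levels named numeric of length 4^k; names are the k-mers over
#'   ACGT in lexicographic order.
#' @slot id free-text identifier recorded in indexes built from this model.
#' @export
setClass("PoreModel",
  representation(k = "integer", levels = "numeric", id = "character"),
  validity = function(object) {
    k <- object@k
    if (length(k) != 1L || is.na(k) || k < 1L)
      return("k must be a single positive integer")
    if (length(object@levels) != 4^k)
      return(sprintf("levels must have exactly 4^k = %d entries", 4^k))
    nm <- names(object@levels)
    if (is.null(nm) || !identical(nm, .all_kmers(k)))
      return("levels must be named by all k-mers in A<C<G<T order")
    if (anyNA(object@levels) || !all(is.finite(object@levels)))
      return("levels must be finite numbers")
    TRUE
  })

#' EventSeries: ordered event values with their positions
#'
#' One value per event. For reference-derived series, `positions` are the
#' 0-based k-mer start positions; k-mers containing ambiguous bases produce
#' NA values so that positions stay absolute. For signal-derived series,
#' positions are 0-based event ranks.
#'
#' @slot values numeric event values (NA where no event exists).
#' @slot positions 0-based integer positions, same length as values.
#' @slot source reference sequence id or read id.
#' @slot normalized TRUE once z-scored (population sd).
#' @export
setClass("EventSeries",
  representation(values = "numeric", positions = "integer",
                 source = "character", normalized = "logical"),
  validity = function(object) {
    if (length(object@values) != length(object@positions))
      return("values and positions must have equal length")
    if (length(object@normalized) != 1L)
      return("normalized must be a single flag")
    if (isTRUE(object@normalized)) {
      v <- object@values[!is.na(object@values)]
      if (length(v) >= 2L) {
        if (abs(mean(v)) > 1e-6) return("normalized series must have mean 0")
        if (abs(sqrt(mean((v - mean(v))^2)) - 1) > 1e-6)
          return("normalized series must have unit (population) sd")
      }
    }
    TRUE
  })

#' ReferenceIndex: 32-bit seed hash table over a reference genome
#'
#' Buckets of (target, position, strand) hits keyed by the 32-bit hash of n
#' consecutive quantized reference events, both strands. Positions are
#' forward-coordinate event indices (k-mer start positions). Built by
#' [buildIndex()]; queried with [queryIndex()].
#'
#' @slot keys sorted unique hash values (stored as doubles, 32-bit range).
#' @slot bucketStarts 1-based offsets into the hit vectors, length
#'   `length(keys) + 1`.
#' @slot hitTarget,hitPos,hitStrand parallel hit vectors; strand is +1/-1.
#' @slot targetNames,targetLengths,targetEvents per-target directory
#'   (lengths in bases, event counts = length - k + 1).
#' @slot k,Q,p,n indexing parameters (k-mer size; quantization bits Q and
#'   pruned bits p; events per seed n).
#' @slot maskFraction fraction of the most frequent hashes masked out.
#' @slot maskedCount number of hits dropped by masking.
#' @slot modelId id of the pore model the index was built with.
#' @export
setClass("ReferenceIndex",
  representation(keys = "numeric", bucketStarts = "integer",
                 hitTarget = "integer", hitPos = "integer",
                 hitStrand = "integer",
                 targetNames = "character", targetLengths = "integer",
                 targetEvents = "integer",
                 k = "integer", Q = "integer", p = "integer", n = "integer",
                 maskFraction = "numeric", maskedCount = "numeric",
                 modelId = "character"),
  validity = function(object) {
    if (length(object@bucketStarts) != length(object@keys) + 1L)
      return("bucketStarts must have length(keys) + 1 entries")
    nh <- length(object@hitTarget)
    if (length(object@hitPos) != nh || length(object@hitStrand) != nh)
      return("hit vectors must have equal length")
    if (nh > 0 && object@bucketStarts[length(object@bucketStarts)] != nh + 1L)
      return("bucketStarts must close at the number of hits + 1")
    if (is.unsorted(object@keys, strictly = TRUE) && length(object@keys) > 1)
      return("keys must be strictly increasing")
    if (!(2 + object@p < object@Q))
      return("quantization requires 2 + p < Q")
    TRUE
  })

#' @describeIn PoreModel k-mer length of the model
#' @param object,x a `PoreModel`
#' @export
kmerSize <- function(x) {
  stopifnot(is(x, "PoreModel") || is(x, "ReferenceIndex"))
  if (is(x, "PoreModel")) x@k else x@k
}

#' @describeIn PoreModel named vector of expected mean levels
#' @export
levelMeans <- function(x) {
  stopifnot(is(x, "PoreModel"))
  x@levels
}

#' @describeIn PoreModel model identifier
#' @export
modelId <- function(x) {
  if (is(x, "PoreModel")) x@id else if (is(x, "ReferenceIndex")) x@modelId
  else stop("no model id for this object")
}

setMethod("show", "PoreModel", function(object) {
  cat(sprintf("PoreModel '%s': k = %d, %d k-mer levels in [%.2f, %.2f]\n",
              object@id, object@k, length(object@levels),
              min(object@levels), max(object@levels)))
})

#' @describeIn EventSeries number of event slots (including NA gaps)
#' @param x an `EventSeries`
#' @export
setMethod("length", "EventSeries", function(x) length(x@values))

#' @describeIn EventSeries event values
#' @export
eventValues <- function(x) {
  stopifnot(is(x, "EventSeries"))
  x@values
}

#' @describeIn EventSeries 0-based event positions
#' @export
eventPositions <- function(x) {
  stopifnot(is(x, "EventSeries"))
  x@positions
}

#' @describeIn EventSeries whether the series has been z-scored
#' @export
isNormalized <- function(x) {
  stopifnot(is(x, "EventSeries"))
  isTRUE(x@normalized)
}

setMethod("show", "EventSeries", function(object) {
  cat(sprintf("EventSeries '%s': %d events (%d NA), %s\n", object@source,
              length(object@values), sum(is.na(object@values)),
              if (isTRUE(object@normalized)) "normalized" else "raw"))
})

#' @describeIn ReferenceIndex target names in index order
#' @export
targetNames <- function(x) {
  stopifnot(is(x, "ReferenceIndex"))
  x@targetNames
}

#' @describeIn ReferenceIndex target lengths in bases, named
#' @export
targetLengths <- function(x) {
  stopifnot(is(x, "ReferenceIndex"))
  stats::setNames(x@targetLengths, x@targetNames)
}

#' @describeIn ReferenceIndex indexing parameters as a named list
#' @export
indexParams <- function(x) {
  stopifnot(is(x, "ReferenceIndex"))
  list(k = x@k, Q = x@Q, p = x@p, n = x@n,
       maskFraction = x@maskFraction, modelId = x@modelId)
}

setMethod("show", "ReferenceIndex", function(object) {
  cat(sprintf(paste0(
    "ReferenceIndex: %d targets, %s hits in %s buckets\n",
    "  k = %d, Q = %d, p = %d, n = %d (seed width %d bits)\n",
    "  model '%s'; %s hits masked (top %.3g%% buckets)\n"),
    length(object@targetNames),
    format(length(object@hitTarget), big.mark = ","),
    format(length(object@keys), big.mark = ","),
    object@k, object@Q, object@p, object@n,
    object@n * (object@Q - object@p),
    object@modelId, format(object@maskedCount, big.mark = ","),
    100 * object@maskFraction))
})
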