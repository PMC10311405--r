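#' Quantization parameters
#'
#' A normalized event value is reduced to a small integer code by taking the
#' most significant `Q` bits of its IEEE-754 single-precision bit pattern
#' (bit 1 = sign, MSB-first) and pruning `p` bits immediately after the top
#' two bits, leaving the `Q - p`-bit code `E[1,2]E[3+p,Q]`. Values that are
#' close on the normalized scale — mostly within [-3, 3] — deliberately
#' collide, which is what makes exact hash matching of noisy events work.
#' The constraint `2 + p < Q` must hold.
#'
#' @param Q most significant bits retained (<= 32).
#' @param p bits pruned after the top two bits (>= 0).
#' @return a named list of class `QuantizationParams` with the code `width`.
#' @export
quantizationParams <- function(Q = 9L, p = 4L) {
  Q <- as.integer(Q); p <- as.integer(p)
  if (p < 0L) stop("p must be >= 0")
  if (Q > 32L) stop("Q must be <= 32")
  if (!(2L + p < Q)) stop("quantization requires 2 + p < Q")
  if (Q - p > 31L) stop("code width Q - p must be <= 31")
  structure(list(Q = Q, p = p, width = Q - p), class = "QuantizationParams")
}

#' Quantize normalized event values
#'
#' Converts each value to its single-precision bit pattern (negative zero
#' canonicalized to +0) and slices out the `Q - p` code bits. Equal retained
#' bits give equal codes; the sign bit is always kept, so `v` and `-v` never
#' collide for `v != 0`. NA values propagate (reference positions whose
#' k-mer contains an ambiguous base).
#'
#' @param values finite numeric event values (z-scored).
#' @param params a [quantizationParams()] list.
#' @return integer codes in `[0, 2^(Q-p))`.
#' @export
quantizeEvents <- function(values, params = quantizationParams()) {
  cpp_quantize(as.numeric(values), params$Q, params$p)
}
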