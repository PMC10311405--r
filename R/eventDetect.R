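#' Segmentation parameters
#'
#' Event boundaries are called where the Welch t-statistic between the
#' adjacent rolling windows exceeds a threshold and is a local peak; two
#' window lengths are combined (union of boundary sets) to stay robust
#' against varying translocation speed (skip/stay errors). Defaults follow
#' the short/long-window segmentation style of squiggle basecallers and are
#' calibrated so that noise-free simulated signals are segmented into one
#' event per k-mer step.
#'
#' @param window_short,window_long window lengths in samples (>= 2).
#' @param t_short,t_long t-statistic thresholds paired with the windows.
#' @param min_len segments shorter than this many samples are discarded
#'   (mitigates stay/spike artifacts).
#' @return a named list of class `SegmentationParams`.
#' @export
segmentationParams <- function(window_short = 3L, window_long = 6L,
                               t_short = 4.3, t_long = 2.57, min_len = 3L) {
  window_short <- as.integer(window_short)
  window_long <- as.integer(window_long)
  if (window_short < 2L || window_long < 2L)
    stop("segmentation windows must be >= 2 samples")
  if (!(t_short > 0 && t_long > 0)) stop("t thresholds must be positive")
  if (min_len < 1L) stop("min_len must be >= 1")
  structure(list(window_short = window_short, window_long = window_long,
                 t_short = t_short, t_long = t_long,
                 min_len = as.integer(min_len)),
            class = "SegmentationParams")
}

#' Detect event boundaries in a raw signal
#'
#' Computes the Welch t-statistic between `samples[i-w, i)` and
#' `samples[i, i+w)` for each window length `w`, calls `i` a boundary when
#' the statistic exceeds that window's threshold and is a local peak, and
#' returns the union of the per-window boundary sets.
#'
#' @param samples numeric raw current samples.
#' @param params a [segmentationParams()] list.
#' @return sorted 0-based boundary offsets; empty when the signal is shorter
#'   than `2 * max(window) + 1` (callers should buffer more samples).
#' @export
detectBoundaries <- function(samples, params = segmentationParams()) {
  wmax <- max(params$window_short, params$window_long)
  if (length(samples) <= 2L * wmax) return(integer(0))
  cpp_detect_boundaries(as.numeric(samples),
                        c(params$window_short, params$window_long),
                        c(params$t_short, params$t_long))
}

#' Summarize segments between boundaries as events
#'
#' Consecutive boundary offsets partition the sample range; each segment
#' becomes one event summarized by the arithmetic mean of its samples.
#' Segments shorter than `min_len` samples are discarded.
#'
#' @param samples numeric raw samples.
#' @param boundaries sorted 0-based offsets strictly inside the range.
#' @param min_len minimum segment length in samples.
#' @return data.frame with 0-based `start`, `length`, `mean` per event.
#' @export
segmentsToEvents <- function(samples, boundaries, min_len = 1L) {
  ev <- cpp_segments_to_events(as.numeric(samples), as.integer(boundaries),
                               as.integer(min_len))
  data.frame(start = ev$start, length = ev$length, mean = ev$mean)
}

#' Detect events in a raw signal buffer
#'
#' Convenience wrapper: [detectBoundaries()] followed by
#' [segmentsToEvents()] with the parameter set's `min_len`.
#'
#' @inheritParams detectBoundaries
#' @return data.frame with `start`, `length`, `mean` per event.
#' @export
detectEvents <- function(samples, params = segmentationParams()) {
  segmentsToEvents(samples, detectBoundaries(samples, params),
                   params$min_len)
}

#' Normalize the events of one time chunk
#'
#' Z-scores (population sd) the mean event values produced within one
#' streaming interval — by default the events from one second of signal —
#' mirroring the per-contig normalization of the reference side.
#'
#' @param means numeric mean event values of the current chunk (>= 2).
#' @param source label for the returned series.
#' @return a normalized [EventSeries-class].
#' @export
normalizeChunkEvents <- function(means, source = "chunk") {
  if (length(means) < 2L)
    stop("a chunk needs at least two events to normalize; ",
         "buffer and merge with the next chunk")
  new("EventSeries", values = .zscore(as.numeric(means)),
      positions = 0:(length(means) - 1L), source = source, normalized = TRUE)
}
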