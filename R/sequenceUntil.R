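#' Sequence Until parameters
#'
#' Relative abundance is re-estimated after every `estimate_every` mapped
#' reads; the last `window_w` estimates are compared by normalized
#' cross-correlation (cosine similarity of each estimate against the mean
#' of the other `w - 1`). When no estimate in the window is an outlier —
#' every similarity is at least `outlier_threshold` — the estimation has
#' converged and the whole sequencing run can be stopped (Run Until).
#'
#' @param estimate_every mapped reads between estimates.
#' @param window_w recent estimates compared (>= 3).
#' @param outlier_threshold minimum similarity for a non-outlier.
#' @return a named list of class `SequenceUntilParams`.
#' @export
sequenceUntilParams <- function(estimate_every = 500L, window_w = 5L,
                                outlier_threshold = 0.99) {
  estimate_every <- as.integer(estimate_every)
  window_w <- as.integer(window_w)
  if (estimate_every < 1L) stop("estimate_every must be >= 1")
  if (window_w < 3L) stop("window_w must be >= 3")
  if (outlier_threshold <= 0 || outlier_threshold > 1)
    stop("outlier_threshold must be in (0, 1]")
  structure(list(estimate_every = estimate_every, window_w = window_w,
                 outlier_threshold = outlier_threshold),
            class = "SequenceUntilParams")
}

#' Fresh abundance state
#'
#' @param taxa optional taxon names to pre-register (counts start at 0).
#' @return a list of class `AbundanceState`: cumulative `counts`, counts
#'   at the last estimate, reads since the last estimate, the estimate
#'   history (most recent last) and the total mapped reads seen.
#' @export
newAbundanceState <- function(taxa = character()) {
  structure(list(counts = stats::setNames(rep(0, length(taxa)), taxa),
                 last_counts = stats::setNames(rep(0, length(taxa)), taxa),
                 since = 0L, history = list(), total = 0L),
            class = "AbundanceState")
}

.count_add <- function(counts, taxon) {
  if (!taxon %in% names(counts)) counts[taxon] <- 0
  counts[taxon] <- counts[taxon] + 1
  counts
}

#' Update the abundance state with one mapping
#'
#' Unmapped reads are ignored; mapped reads increment their taxon's count
#' (taxon resolved from the target id's `taxid|<id>|` prefix, falling back
#' to the target id, and to `"unknown"` when unresolvable). After every
#' `estimate_every` mapped reads the proportions over that interval are
#' appended to the estimate history, keeping the last `window_w`.
#'
#' @param state an `AbundanceState` from [newAbundanceState()].
#' @param mapping one mapping record (a one-row data.frame with `mapped`
#'   and `target`, a PAF row with `tname`, or a target id string).
#' @param params a [sequenceUntilParams()] list.
#' @return the updated state.
#' @export
updateAbundance <- function(state, mapping, params = sequenceUntilParams()) {
  if (is.character(mapping)) {
    target <- mapping
    mapped <- target != "*"
  } else if (!is.null(mapping$mapped)) {
    mapped <- isTRUE(mapping$mapped[1])
    target <- mapping$target[1]
  } else {
    target <- mapping$tname[1]
    mapped <- !is.na(target) && target != "*"
  }
  if (!mapped) return(state)
  taxon <- .target_taxon(target)
  if (is.na(taxon) || !nzchar(taxon)) taxon <- "unknown"
  state$counts <- .count_add(state$counts, taxon)
  state$total <- state$total + 1L
  state$since <- state$since + 1L
  if (state$since >= params$estimate_every) {
    taxa <- names(state$counts)
    last <- stats::setNames(rep(0, length(taxa)), taxa)
    last[names(state$last_counts)] <- state$last_counts
    interval <- state$counts - last
    est <- interval / sum(interval)
    state$history <- c(state$history, list(est))
    if (length(state$history) > params$window_w)
      state$history <- state$history[-1L]
    state$last_counts <- state$counts
    state$since <- 0L
  }
  state
}

#' Cumulative abundance estimate of a state
#'
#' @param state an `AbundanceState`.
#' @return named proportions over all mapped reads seen (empty-sum safe).
#' @export
abundanceEstimate <- function(state) {
  if (state$total == 0L) return(state$counts)
  state$counts / sum(state$counts)
}

.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Convergence test over the last w abundance estimates
#'
#' Each estimate vector is compared against the mean of the other `w - 1`
#' by normalized cross-correlation; an estimate is an outlier when its
#' similarity falls below the threshold. The window has converged — and
#' sequencing can stop — exactly when no estimate is an outlier. With
#' fewer than `window_w` estimates the answer is always FALSE.
#'
#' @param history list of named abundance vectors (or a matrix with one
#'   estimate per row).
#' @param params a [sequenceUntilParams()] list.
#' @return TRUE when converged.
#' @export
isConverged <- function(history, params = sequenceUntilParams()) {
  if (is.matrix(history))
    history <- lapply(seq_len(nrow(history)), function(i) history[i, ])
  if (length(history) < params$window_w) return(FALSE)
  history <- utils::tail(history, params$window_w)
  taxa <- unique(unlist(lapply(history, names)))
  mat <- if (is.null(taxa)) {
    do.call(rbind, history)
  } else {
    m <- matrix(0, length(history), length(taxa),
                dimnames = list(NULL, taxa))
    for (i in seq_along(history)) m[i, names(history[[i]])] <- history[[i]]
    m
  }
  w <- nrow(mat)
  for (i in seq_len(w)) {
    others <- colMeans(mat[-i, , drop = FALSE])
    if (.cosine(mat[i, ], others) < params$outlier_threshold) return(FALSE)
  }
  TRUE
}

#' Run Sequence Until over a stream of mapping records
#'
#' Consumes mapping records in arrival order, maintaining the abundance
#' state, and stops at the first converged estimate window (the Run Until
#' surrogate) or at stream end.
#'
#' @param mappings data.frame of mapping records in arrival order (from
#'   [mapReads()], a PAF data.frame, or anything with `mapped`/`target`
#'   columns).
#' @param params a [sequenceUntilParams()] list.
#' @return list: `estimate` (cumulative proportions at stop), `counts`,
#'   `reads_consumed` (stream records consumed, mapped or not),
#'   `fraction_consumed`, `stopped_early`, `n_estimates`.
#' @export
runSequenceUntil <- function(mappings, params = sequenceUntilParams()) {
  n <- nrow(mappings)
  if (is.null(n) || n == 0L) {
    return(list(estimate = numeric(0), counts = numeric(0),
                reads_consumed = 0L, fraction_consumed = 0,
                stopped_early = FALSE, n_estimates = 0L))
  }
  if (!is.null(mappings$mapped)) {
    mapped <- mappings$mapped
    target <- mappings$target
  } else {
    target <- mappings$tname
    mapped <- !is.na(target) & target != "*"
  }
  taxon <- .target_taxon(target)
  taxon[is.na(taxon) | !nzchar(taxon)] <- "unknown"
  state <- newAbundanceState()
  consumed <- n
  stopped <- FALSE
  for (i in seq_len(n)) {
    if (!mapped[i]) next
    state$counts <- .count_add(state$counts, taxon[i])
    state$total <- state$total + 1L
    state$since <- state$since + 1L
    if (state$since >= params$estimate_every) {
      taxa <- names(state$counts)
      last <- stats::setNames(rep(0, length(taxa)), taxa)
      last[names(state$last_counts)] <- state$last_counts
      interval <- state$counts - last
      state$history <- c(state$history, list(interval / sum(interval)))
      if (length(state$history) > params$window_w)
        state$history <- state$history[-1L]
      state$last_counts <- state$counts
      state$since <- 0L
      if (isConverged(state$history, params)) {
        consumed <- i
        stopped <- TRUE
        break
      }
    }
  }
  list(estimate = abundanceEstimate(state), counts = state$counts,
       reads_consumed = consumed, fraction_consumed = consumed / n,
       stopped_early = stopped, n_estimates = length(state$history))
}
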