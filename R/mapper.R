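#' Chaining and mapping-decision parameters
#'
#' Anchors (seed matches) are chained by dynamic programming:
#' `f(j) = match_score + max(0, max_i f(i) - gap_scale * |dT - dQ|)` over
#' admissible predecessors (same target and strand, both coordinates
#' strictly increasing, both deltas <= `max_gap`), with no per-anchor
#' distance coefficient. A read is accepted in the current chunk when the
#' best chain reaches `min_chain_score` and beats the best chain from any
#' other region by `best_ratio`.
#'
#' @param match_score score contributed by each chained anchor.
#' @param gap_scale gap cost per unit of |dT - dQ| (default 1% of
#'   `match_score`).
#' @param max_gap maximum anchor-to-anchor gap, in events/positions.
#' @param max_skip bound on predecessor look-back in the DP.
#' @param min_chain_score minimum best-chain score to accept a mapping.
#' @param best_ratio required ratio of best over second-best chain score,
#'   the second best taken from a different target/strand or a
#'   non-overlapping region.
#' @param max_chunks give up and report unmapped after this many chunks.
#' @param max_chains chains reported per chaining round.
#' @return a named list of class `ChainParams`.
#' @export
chainParams <- function(match_score = 1, gap_scale = 0.01 * match_score,
                        max_gap = 2000L, max_skip = 25L,
                        min_chain_score = 15, best_ratio = 1.2,
                        max_chunks = 10L, max_chains = 5L) {
  if (match_score <= 0 || gap_scale < 0) stop("scores must be positive")
  if (best_ratio < 1) stop("best_ratio must be >= 1")
  if (max_gap < 1 || max_skip < 1 || max_chunks < 1)
    stop("max_gap, max_skip and max_chunks must be positive")
  structure(list(match_score = match_score, gap_scale = gap_scale,
                 max_gap = as.integer(max_gap),
                 max_skip = as.integer(max_skip),
                 min_chain_score = min_chain_score,
                 best_ratio = best_ratio, max_chunks = as.integer(max_chunks),
                 max_chains = as.integer(max_chains)),
            class = "ChainParams")
}

#' Collect anchors for a stream of read events
#'
#' Quantizes the normalized read events with the index's parameters, hashes
#' every window of `n` consecutive codes and queries the index; each hit
#' becomes one anchor. Reverse-strand hits are given a chain coordinate
#' that increases with read progress so that chaining treats both strands
#' uniformly.
#'
#' @param events normalized [EventSeries-class] or numeric vector of
#'   normalized event values.
#' @param index a [ReferenceIndex-class].
#' @param qidx_offset 0-based rank of the first event in the full read
#'   stream (for chunked calls).
#' @return data.frame of anchors: `qidx` (0-based window start in read
#'   events), `tid`, `pos` (forward event coordinate), `strand`, `cpos`
#'   (chain coordinate), sorted by (tid, strand, cpos, qidx).
#' @export
collectAnchors <- function(events, index, qidx_offset = 0L) {
  vals <- if (is(events, "EventSeries")) events@values else as.numeric(events)
  codes <- cpp_quantize(vals, index@Q, index@p)
  .anchors_from_codes(codes, index, qidx_offset)
}

.anchors_from_codes <- function(codes, index, qidx_offset = 0L,
                                from_window = 0L) {
  n <- index@n
  empty <- data.frame(qidx = integer(0), tid = integer(0), pos = integer(0),
                      strand = integer(0), cpos = integer(0))
  if (length(codes) < n) return(empty)
  h <- cpp_seed_hashes(codes, n, index@Q - index@p)
  starts0 <- seq_along(h) - 1L
  sel <- starts0 >= from_window
  if (!any(sel)) return(empty)
  hits <- queryIndex(index, h[sel])
  if (nrow(hits) == 0L) return(empty)
  qidx <- starts0[sel][hits$query] + as.integer(qidx_offset)
  cpos <- ifelse(hits$strand == 1L, hits$pos,
                 index@targetEvents[hits$tid] - n - hits$pos)
  a <- data.frame(qidx = qidx, tid = hits$tid, pos = hits$pos,
                  strand = hits$strand, cpos = as.integer(cpos))
  a[order(a$tid, a$strand, a$cpos, a$qidx), , drop = FALSE]
}

#' Chain anchors into scored colinear placements
#'
#' Runs the chaining DP over the anchors and backtracks the best chains,
#' each anchor used by at most one chain. Ties are broken deterministically
#' (lexicographically smaller target, then smaller start).
#'
#' @param anchors data.frame as returned by [collectAnchors()].
#' @param index the [ReferenceIndex-class] the anchors came from (for
#'   coordinate conversion).
#' @param params a [chainParams()] list.
#' @return data.frame of chains in descending score: `score`, `tid`,
#'   `target`, `strand` (+1/-1), `tstart`/`tend` (forward base
#'   coordinates, 0-based half-open), `qstart`/`qend` (read event
#'   coordinates, half-open), `n_anchors`.
#' @export
chainAnchors <- function(anchors, index, params = chainParams()) {
  if (is.null(anchors) || nrow(anchors) == 0L) {
    return(data.frame(score = numeric(0), tid = integer(0),
                      target = character(0), strand = integer(0),
                      tstart = integer(0), tend = integer(0),
                      qstart = integer(0), qend = integer(0),
                      n_anchors = integer(0)))
  }
  o <- order(anchors$tid, anchors$strand, anchors$cpos, anchors$qidx)
  a <- anchors[o, , drop = FALSE]
  res <- cpp_chain_anchors(a$tid, a$strand, a$cpos, a$qidx,
                           params$match_score, params$gap_scale,
                           params$max_gap, params$max_skip,
                           params$max_chains)
  if (length(res$score) == 0L) {
    return(chainAnchors(NULL, index, params))
  }
  n <- index@n
  k <- index@k
  E <- index@targetEvents[res$tid]
  fwd <- res$strand == 1L
  ev_start <- ifelse(fwd, res$cstart, E - n - res$cend)
  ev_end <- ifelse(fwd, res$cend + n - 1L, (E - n - res$cstart) + n - 1L)
  ch <- data.frame(score = res$score, tid = res$tid,
                   target = index@targetNames[res$tid],
                   strand = res$strand,
                   tstart = as.integer(ev_start),
                   tend = as.integer(ev_end + k),
                   qstart = res$qstart, qend = res$qend + n,
                   n_anchors = res$n_anchors)
  ch[order(-ch$score, ch$target, ch$tstart), , drop = FALSE]
}

# best/second-best decision; the second-best chain must come from a
# different target/strand or a region overlapping the best by < 50%
.decide_mapping <- function(chains, params) {
  if (nrow(chains) == 0L) return(list(accept = FALSE))
  best <- chains[1L, ]
  second <- NA_real_
  if (nrow(chains) > 1L) {
    for (i in 2:nrow(chains)) {
      ci <- chains[i, ]
      if (ci$tid != best$tid || ci$strand != best$strand) {
        second <- ci$score; break
      }
      ov <- min(best$tend, ci$tend) - max(best$tstart, ci$tstart)
      shorter <- min(best$tend - best$tstart, ci$tend - ci$tstart)
      if (ov < 0.5 * shorter) { second <- ci$score; break }
    }
  }
  accept <- best$score >= params$min_chain_score &&
    (is.na(second) || best$score / second >= params$best_ratio)
  list(accept = accept, best = best, second = second)
}

.unmapped_row <- function(read_id, chunks_used, events_used) {
  data.frame(read_id = read_id, mapped = FALSE, target = "*", strand = "*",
             tstart = 0L, tend = 0L, qstart = 0L, qend = 0L,
             score = 0, n_anchors = 0L, chunks_used = chunks_used,
             events_used = events_used, stringsAsFactors = FALSE)
}

#' Map one raw signal in streaming chunks
#'
#' Consumes the signal one chunk (default one second of samples) at a time:
#' segments it into events (holding back the unterminated tail segment and
#' a left context between chunks), z-scores the chunk's event means,
#' quantizes them, extends the anchor set by querying the index with the
#' newly available seed windows, and re-chains over all anchors seen so
#' far. The read is accepted as soon as the best chain passes the score and
#' best/second-best ratio tests — the Read Until surrogate: remaining
#' chunks are not consumed. After `max_chunks` chunks without acceptance
#' the read is reported unmapped.
#'
#' @param samples numeric raw current samples of the full read (the
#'   streaming source).
#' @param index a [ReferenceIndex-class].
#' @param params a [chainParams()] list.
#' @param seg a [segmentationParams()] list.
#' @param sample_rate raw samples per second.
#' @param chunk_seconds chunk duration; one second by default.
#' @param read_id read name for the output record.
#' @return one-row data.frame: `read_id`, `mapped`, `target`, `strand`
#'   ("+"/"-"/"*"), `tstart`/`tend` (0-based half-open base coordinates),
#'   `qstart`/`qend` (consumed read events), `score`, `n_anchors`,
#'   `chunks_used`, `events_used`.
#' @export
mapSignal <- function(samples, index, params = chainParams(),
                      seg = segmentationParams(), sample_rate = 4000,
                      chunk_seconds = 1, read_id = "read") {
  stopifnot(is(index, "ReferenceIndex"))
  chunk_len <- max(1, min(round(sample_rate * chunk_seconds),
                          max(1, length(samples))))
  chunk_len <- as.integer(chunk_len)
  n_total <- ceiling(length(samples) / chunk_len)
  n_proc <- min(n_total, params$max_chunks)
  if (length(samples) == 0L) return(.unmapped_row(read_id, 0L, 0L))
  pending <- numeric(0)
  carry <- numeric(0)
  codes <- integer(0)
  anchors <- NULL
  next_window <- 0L
  for (ci in seq_len(n_proc)) {
    a <- (ci - 1L) * chunk_len + 1L
    b <- min(ci * chunk_len, length(samples))
    buf <- c(pending, samples[a:b])
    final <- ci == n_total
    bnd <- detectBoundaries(buf, seg)
    if (final) {
      ev <- segmentsToEvents(buf, bnd, seg$min_len)
      pending <- numeric(0)
    } else if (length(bnd) == 0L) {
      ev <- data.frame(start = integer(0), length = integer(0),
                       mean = numeric(0))
      pending <- buf
    } else {
      last <- max(bnd)
      ev <- segmentsToEvents(buf[seq_len(last)], bnd[bnd < last],
                             seg$min_len)
      pending <- buf[(last + 1L):length(buf)]
    }
    means <- c(carry, ev$mean)
    if (length(means) >= 2L) {
      codes <- c(codes, cpp_quantize(.zscore(means), index@Q, index@p))
      carry <- numeric(0)
    } else {
      carry <- means
      next
    }
    new_anchors <- .anchors_from_codes(codes, index,
                                       from_window = next_window)
    next_window <- max(next_window, length(codes) - index@n + 1L)
    if (nrow(new_anchors) > 0L)
      anchors <- if (is.null(anchors)) new_anchors
                 else rbind(anchors, new_anchors)
    if (is.null(anchors) || nrow(anchors) == 0L) next
    chains <- chainAnchors(anchors, index, params)
    dec <- .decide_mapping(chains, params)
    if (dec$accept) {
      bst <- dec$best
      return(data.frame(read_id = read_id, mapped = TRUE,
                        target = bst$target,
                        strand = if (bst$strand == 1L) "+" else "-",
                        tstart = bst$tstart, tend = bst$tend,
                        qstart = bst$qstart, qend = bst$qend,
                        score = bst$score, n_anchors = bst$n_anchors,
                        chunks_used = ci, events_used = length(codes),
                        stringsAsFactors = FALSE))
    }
  }
  .unmapped_row(read_id, n_proc, length(codes))
}

#' Map a set of raw signal reads
#'
#' Applies [mapSignal()] to each read of a signal file or in-memory read
#' list and returns one mapping record per read.
#'
#' @param signals path to a signal text file (see [readSignals()]) or a
#'   list of reads, each a list with `read_id`, `sample_rate`, `samples`.
#' @inheritParams mapSignal
#' @param verbose print a progress line every 100 reads.
#' @return data.frame of mapping records (one row per read).
#' @export
mapReads <- function(signals, index, params = chainParams(),
                     seg = segmentationParams(), chunk_seconds = 1,
                     verbose = FALSE) {
  reads <- if (is.character(signals)) readSignals(signals) else signals
  out <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    r <- reads[[i]]
    out[[i]] <- mapSignal(r$samples, index, params, seg,
                          sample_rate = r$sample_rate,
                          chunk_seconds = chunk_seconds,
                          read_id = r$read_id)
    if (verbose && i %% 100 == 0)
      message(sprintf("mapped %d/%d reads", i, length(reads)))
  }
  do.call(rbind, out)
}

#' Convert mapping records to a PAF data.frame
#'
#' Query coordinates are in consumed read events (one event advances one
#' base through the pore, so event counts stand in for base counts); target
#' coordinates are 0-based half-open base positions with the k-mer span
#' included at the end. Chain score, chunks used and events used travel as
#' `sc:f`, `ch:i` and `ev:i` tags. Unmapped reads keep the `*` target
#' convention.
#'
#' @param mappings data.frame from [mapReads()].
#' @param index the index used for mapping (target lengths).
#' @return PAF-shaped data.frame accepted by [writePaf()].
#' @export
mappingsToPaf <- function(mappings, index) {
  tl <- targetLengths(index)
  mapped <- mappings$mapped
  data.frame(
    qname = mappings$read_id,
    qlen = mappings$events_used,
    qstart = mappings$qstart,
    qend = mappings$qend,
    strand = mappings$strand,
    tname = mappings$target,
    tlen = ifelse(mapped, unname(tl[mappings$target]), 0L),
    tstart = mappings$tstart,
    tend = mappings$tend,
    nmatch = mappings$n_anchors,
    alen = pmax(mappings$tend - mappings$tstart,
                mappings$qend - mappings$qstart),
    mapq = ifelse(mapped, 60L, 0L),
    score = mappings$score,
    chunks_used = mappings$chunks_used,
    events_used = mappings$events_used,
    stringsAsFactors = FALSE)
}
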