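#' Simulation parameters
#'
#' Models the signal-generation physics the mapper has to undo: a strand
#' translocates at ~450 bases per second while the current is sampled at
#' 4 kHz, so each k-mer dwells for ~8.9 samples on average; dwell times
#' jitter (dispersion as a coefficient of variation), Gaussian amplitude
#' noise rides on the pore-model level, and k-mers may dwell twice (stay)
#' or pass undetected (skip).
#'
#' @param bases_per_second pore translocation speed.
#' @param sample_rate raw samples per second.
#' @param dwell_dispersion coefficient of variation of samples-per-base.
#' @param noise_sd Gaussian amplitude noise, in model-level units.
#' @param p_stay probability a k-mer's dwell is duplicated.
#' @param p_skip probability a k-mer is dropped.
#' @param read_length_mean,read_length_sd,read_length_min read length draw
#'   (bases, normal truncated below at `read_length_min`).
#' @param seed RNG seed for run-level determinism.
#' @return a named list of class `SimParams`.
#' @export
simParams <- function(bases_per_second = 450, sample_rate = 4000,
                      dwell_dispersion = 0.3, noise_sd = 0.25,
                      p_stay = 0.05, p_skip = 0.05,
                      read_length_mean = 1500, read_length_sd = 500,
                      read_length_min = 200, seed = NULL) {
  if (bases_per_second <= 0 || sample_rate <= 0)
    stop("rates must be positive")
  for (p in c(p_stay, p_skip))
    if (p < 0 || p >= 1) stop("probabilities must be in [0, 1)")
  structure(list(bases_per_second = bases_per_second,
                 sample_rate = sample_rate,
                 dwell_dispersion = dwell_dispersion, noise_sd = noise_sd,
                 p_stay = p_stay, p_skip = p_skip,
                 read_length_mean = read_length_mean,
                 read_length_sd = read_length_sd,
                 read_length_min = read_length_min, seed = seed),
            class = "SimParams")
}

# taxon id from a FASTA record id: "taxid|<id>|..." prefix, else the id
.target_taxon <- function(target_id) {
  ifelse(grepl("^taxid\\|", target_id),
         vapply(strsplit(target_id, "|", fixed = TRUE),
                function(x) if (length(x) >= 2 && nzchar(x[2])) x[2]
                            else "unknown", character(1)),
         target_id)
}

#' Simulate the raw signal of one read
#'
#' Draws an origin (uniform over the reference, length-weighted across
#' targets, both strands) unless given, walks the k-mers of the traversed
#' sequence emitting one dwell of noisy samples per k-mer at the
#' pore-model level, and applies stay (duplicated dwell) and skip (dropped
#' k-mer) errors independently. Deterministic under a fixed seed.
#'
#' @param reference FASTA path or `Biostrings::DNAStringSet`.
#' @param model a [PoreModel-class].
#' @param params a [simParams()] list.
#' @param origin optional list with `target` (name), `strand` ("+"/"-"),
#'   `start` (0-based forward base), `length` (bases).
#' @param read_id read name.
#' @param seed per-read seed (NULL = current RNG state).
#' @return list with `read_id`, `samples`, `sample_rate`, `truth` (list
#'   `target`, `strand`, `start`, `end` in forward base coordinates),
#'   `n_kmers` emitted and `dwell_ends` (sample offset at the end of each
#'   emitted k-mer's dwell).
#' @export
simulateRead <- function(reference, model, params = simParams(),
                         origin = NULL, read_id = "sim_read",
                         seed = params$seed) {
  ref <- if (is.character(reference)) {
    Biostrings::readDNAStringSet(reference)
  } else reference
  names(ref) <- sub("\\s.*$", "", names(ref))
  k <- model@k
  .with_seed(seed, {
    if (is.null(origin)) {
      len <- max(params$read_length_min,
                 round(stats::rnorm(1, params$read_length_mean,
                                    params$read_length_sd)))
      widths <- Biostrings::width(ref)
      ok <- widths >= len + k
      if (!any(ok)) stop("no reference target longer than the read length")
      cand <- which(ok)
      t <- if (length(cand) == 1L) cand
           else sample(cand, 1, prob = widths[cand])
      start <- sample.int(widths[t] - len + 1L, 1) - 1L
      origin <- list(target = names(ref)[t],
                     strand = if (stats::runif(1) < 0.5) "+" else "-",
                     start = start, length = len)
    }
    t <- match(origin$target, names(ref))
    if (is.na(t)) stop("origin target not in reference: ", origin$target)
    L <- Biostrings::width(ref)[t]
    if (origin$start < 0 || origin$start + origin$length > L)
      stop("infeasible origin: read interval exceeds target bounds")
    sub <- Biostrings::subseq(ref[[t]], origin$start + 1L,
                              origin$start + origin$length)
    if (origin$strand == "-") sub <- Biostrings::reverseComplement(sub)
    levels <- .ref_event_values(as.character(sub), model)
    if (anyNA(levels))
      stop("simulation requires an unambiguous origin sequence")
    nk <- length(levels)
    spb <- params$sample_rate / params$bases_per_second
    keep <- stats::runif(nk) >= params$p_skip
    dwell <- pmax(1, round(stats::rnorm(nk, spb,
                                        params$dwell_dispersion * spb)))
    dwell <- dwell * (1L + (stats::runif(nk) < params$p_stay))
    levels <- levels[keep]
    dwell <- dwell[keep]
    samples <- rep(levels, dwell)
    if (params$noise_sd > 0)
      samples <- samples + stats::rnorm(length(samples), 0, params$noise_sd)
    list(read_id = read_id, samples = samples,
         sample_rate = params$sample_rate,
         truth = list(target = origin$target, strand = origin$strand,
                      start = origin$start,
                      end = origin$start + origin$length),
         n_kmers = length(levels), dwell_ends = cumsum(dwell))
  })
}

#' Simulate a sequencing run with ground truth
#'
#' Emits `n_reads` reads whose taxon of origin is drawn i.i.d. from
#' `mixture` (arrival order is therefore randomly interleaved across
#' taxa), each simulated by [simulateRead()]. Taxa are resolved from the
#' reference record ids (`taxid|<id>|` prefix, or the record id itself).
#'
#' @param reference FASTA path or `Biostrings::DNAStringSet`.
#' @param model a [PoreModel-class].
#' @param n_reads number of reads.
#' @param params a [simParams()] list.
#' @param mixture named taxon proportions summing to 1, or NULL for
#'   length-weighted sampling over the whole reference.
#' @param signal_path optional path: write the reads as a signal text file.
#' @param truth_path optional path: write the ground truth as PAF.
#' @param seed run-level seed (default `params$seed`).
#' @return invisible list with `reads` (list of simulated reads) and
#'   `truth` (PAF-shaped data.frame of the true origins).
#' @export
simulateRun <- function(reference, model, n_reads, params = simParams(),
                        mixture = NULL, signal_path = NULL,
                        truth_path = NULL, seed = params$seed) {
  ref <- if (is.character(reference)) {
    Biostrings::readDNAStringSet(reference)
  } else reference
  names(ref) <- sub("\\s.*$", "", names(ref))
  taxa <- .target_taxon(names(ref))
  widths <- Biostrings::width(ref)
  if (!is.null(mixture)) {
    if (abs(sum(mixture) - 1) > 1e-6)
      stop("mixture proportions must sum to 1")
    if (!all(names(mixture) %in% taxa))
      stop("mixture taxa absent from the reference: ",
           paste(setdiff(names(mixture), taxa), collapse = ", "))
  }
  .with_seed(seed, {
    reads <- vector("list", n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      sub_ids <- if (is.null(mixture)) seq_along(ref) else {
        tx <- sample(names(mixture), 1, prob = mixture)
        which(taxa == tx)
      }
      r <- simulateRead(ref[sub_ids], model, params,
                        read_id = sprintf("sim_read_%d", i), seed = NULL)
      reads[[i]] <- r
      truth[[i]] <- data.frame(
        qname = r$read_id, qlen = r$truth$end - r$truth$start,
        qstart = 0L, qend = r$truth$end - r$truth$start,
        strand = r$truth$strand, tname = r$truth$target,
        tlen = widths[match(r$truth$target, names(ref))],
        tstart = r$truth$start, tend = r$truth$end,
        nmatch = r$truth$end - r$truth$start,
        alen = r$truth$end - r$truth$start, mapq = 60L,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    if (!is.null(signal_path)) writeSignals(reads, signal_path)
    if (!is.null(truth_path)) writePaf(truth, truth_path)
    invisible(list(reads = reads, truth = truth))
  })
}

#' Write reads to the signal text format
#'
#' One read per line: `read_id <TAB> sample_rate <TAB> s1 s2 s3 ...` with
#' whitespace-separated current samples. A plain-text stand-in for binary
#' squiggle containers; adapters for those formats can emit the same
#' per-read lists instead.
#'
#' @param reads list of reads (`read_id`, `sample_rate`, `samples`).
#' @param path output path.
#' @export
writeSignals <- function(reads, path) {
  lines <- vapply(reads, function(r) {
    paste(r$read_id, r$sample_rate,
          paste(formatC(r$samples, format = "f", digits = 4),
                collapse = " "),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signal text file written by [writeSignals()]
#'
#' @param path input path.
#' @return list of reads (`read_id`, `sample_rate`, `samples`).
#' @export
readSignals <- function(path) {
  lines <- readLines(path)
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
      stop("malformed signal record at line ", i,
           ": expected 3 tab-separated fields")
    samples <- as.numeric(strsplit(trimws(parts[3]), "[ ]+")[[1]])
    if (anyNA(samples))
      stop("non-numeric sample value at line ", i)
    list(read_id = parts[1], sample_rate = as.numeric(parts[2]),
         samples = samples)
  })
}
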