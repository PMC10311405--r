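# k-mer enumeration in A<C<G<T order, consistent with the 2-bit encoding
# A=0, C=1, G=2, T=3 used for fast lookup
.all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  km <- bases
  if (k > 1) for (i in 2:k) km <- as.vector(t(outer(km, bases, paste0)))
  km
}

# utf8 code -> base code lookup (A/a=0, C/c=1, G/g=2, T/t=3, else NA);
# lowercase (soft-masked) bases are treated as their uppercase base
.base_code_table <- local({
  tab <- rep(NA_integer_, 128L)
  tab[utf8ToInt("A") + 1L] <- 0L; tab[utf8ToInt("a") + 1L] <- 0L
  tab[utf8ToInt("C") + 1L] <- 1L; tab[utf8ToInt("c") + 1L] <- 1L
  tab[utf8ToInt("G") + 1L] <- 2L; tab[utf8ToInt("g") + 1L] <- 2L
  tab[utf8ToInt("T") + 1L] <- 3L; tab[utf8ToInt("t") + 1L] <- 3L
  tab
})

.seq_codes <- function(seq) {
  ints <- utf8ToInt(seq)
  if (any(ints > 127L)) stop("non-ASCII character in sequence")
  .base_code_table[ints + 1L]
}

# 0-based k-mer ranks for every position; NA where the window contains an
# ambiguous base
.kmer_ranks <- function(codes, k) {
  L <- length(codes)
  if (L < k) return(integer(0))
  nw <- L - k + 1L
  rank <- numeric(nw)
  bad <- logical(nw)
  for (i in seq_len(k)) {
    ci <- codes[i:(i + nw - 1L)]
    bad <- bad | is.na(ci)
    ci[is.na(ci)] <- 0L
    rank <- rank * 4 + ci
  }
  rank[bad] <- NA_real_
  as.integer(rank)
}

#' Construct a pore model
#'
#' @param k k-mer length.
#' @param levels named numeric of expected mean levels for all 4^k k-mers
#'   (any order; reordered internally).
#' @param id identifier stored with the model.
#' @return a [PoreModel-class] object.
#' @export
poreModel <- function(k, levels, id = "pore_model") {
  k <- as.integer(k)
  want <- .all_kmers(k)
  if (is.null(names(levels))) stop("levels must be named by k-mer")
  idx <- match(want, names(levels))
  if (anyNA(idx)) {
    miss <- want[is.na(idx)]
    stop("pore model is missing ", length(miss), " k-mer(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ..." else "")
  }
  new("PoreModel", k = k, levels = stats::setNames(as.numeric(levels[idx]), want),
      id = as.character(id))
}

#' Load a k-mer pore model from a text table
#'
#' Reads a whitespace/tab-delimited table with at least a k-mer column and a
#' mean level column (ONT-style `kmer` / `level_mean`). A header line is
#' detected by a non-numeric second field; extra columns are ignored. The
#' k-mer length is inferred from the key length and the table must be
#' complete (exactly 4^k rows, one per k-mer).
#'
#' @param path path to the model file.
#' @return a [PoreModel-class] object.
#' @export
loadPoreModel <- function(path) {
  if (!file.exists(path)) stop("pore model file not found: ", path)
  first <- strsplit(trimws(readLines(path, n = 1L)), "[ \t]+")[[1]]
  header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2])))
  tab <- utils::read.table(path, header = header, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (ncol(tab) < 2L) stop("pore model table needs at least two columns")
  kcol <- if (header && "kmer" %in% names(tab)) tab[["kmer"]] else tab[[1]]
  lcol <- if (header && "level_mean" %in% names(tab)) tab[["level_mean"]]
          else tab[[2]]
  kmers <- toupper(as.character(kcol))
  lens <- nchar(kmers)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1])[1]
    stop("inconsistent k-mer length at row ", bad, ": '", kmers[bad], "'")
  }
  k <- lens[1]
  if (!all(grepl("^[ACGT]+$", kmers))) {
    bad <- which(!grepl("^[ACGT]+$", kmers))[1]
    stop("invalid k-mer at row ", bad, ": '", kmers[bad], "'")
  }
  levels <- suppressWarnings(as.numeric(lcol))
  if (anyNA(levels)) {
    bad <- which(is.na(levels))[1]
    stop("non-numeric level at row ", bad, ": '", as.character(lcol[bad]), "'")
  }
  if (anyDuplicated(kmers)) {
    bad <- kmers[duplicated(kmers)][1]
    stop("duplicated k-mer in model: '", bad, "'")
  }
  if (nrow(tab) != 4^k) {
    miss <- setdiff(.all_kmers(k), kmers)
    stop("pore model has ", nrow(tab), " rows but 4^", k, " = ", 4^k,
         " are required; missing: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) ", ..." else "")
  }
  poreModel(k, stats::setNames(levels, kmers), id = basename(path))
}

#' Generate a synthetic pore model
#'
#' Draws one expected level per k-mer i.i.d. from a normal distribution on
#' the picoamp scale typical of published k-mer tables (mean 90, sd 10 by
#' default). Useful for simulation and testing when no chemistry-specific
#' table is at hand; the absolute scale is irrelevant after normalization.
#'
#' @param k k-mer length (default 6).
#' @param seed RNG seed for reproducibility (NULL = use current RNG state).
#' @param level_mean,level_sd distribution of k-mer levels.
#' @return a [PoreModel-class] object.
#' @export
randomPoreModel <- function(k = 6L, seed = NULL, level_mean = 90,
                            level_sd = 10) {
  km <- .all_kmers(k)
  lv <- .with_seed(seed, stats::rnorm(length(km), level_mean, level_sd))
  poreModel(k, stats::setNames(lv, km),
            id = sprintf("synthetic_k%d_seed%s", k,
                         if (is.null(seed)) "NA" else seed))
}

#' Write a pore model to an ONT-style text table
#'
#' @param model a [PoreModel-class].
#' @param path output path.
#' @export
writePoreModel <- function(model, path) {
  stopifnot(is(model, "PoreModel"))
  writeLines(c("kmer\tlevel_mean",
               sprintf("%s\t%.6f", names(model@levels), model@levels)),
             path)
  invisible(path)
}

# raw (unnormalized) expected event values for every k-mer start; NA at
# windows containing ambiguous bases
.ref_event_values <- function(seq, model) {
  ranks <- .kmer_ranks(.seq_codes(seq), model@k)
  out <- rep(NA_real_, length(ranks))
  ok <- !is.na(ranks)
  out[ok] <- unname(model@levels[ranks[ok] + 1L])
  out
}

#' Convert a DNA sequence to expected event values
#'
#' Looks up the pore-model level of every k-mer of `seq`, producing
#' `nchar(seq) - k + 1` event values in order. K-mers containing non-ACGT
#' characters yield NA values (positions stay absolute); lowercase bases are
#' treated as uppercase.
#'
#' @param seq character DNA sequence or a `Biostrings::DNAString`.
#' @param model a [PoreModel-class].
#' @param source label stored on the returned series.
#' @param strict error on non-ACGT characters instead of emitting NA events.
#' @return an unnormalized [EventSeries-class]; empty when `nchar(seq) < k`.
#' @export
seqToEvents <- function(seq, model, source = "seq", strict = FALSE) {
  stopifnot(is(model, "PoreModel"))
  seq <- as.character(seq)
  if (strict && !grepl("^[ACGTacgt]*$", seq))
    stop("sequence contains non-ACGT characters (strict mode)")
  vals <- .ref_event_values(seq, model)
  new("EventSeries", values = vals,
      positions = if (length(vals)) 0:(length(vals) - 1L) else integer(0),
      source = source, normalized = FALSE)
}

#' Z-score normalize an event series
#'
#' Centers and scales the event values to zero mean and unit population
#' standard deviation, the same transform applied to reference contigs and
#' to per-chunk read events, so that the two sides are comparable. NA gaps
#' are preserved.
#'
#' @param series an [EventSeries-class] with at least two non-NA values.
#' @return the normalized series.
#' @export
normalizeEvents <- function(series) {
  stopifnot(is(series, "EventSeries"))
  new("EventSeries", values = .zscore(series@values),
      positions = series@positions, source = series@source,
      normalized = TRUE)
}
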