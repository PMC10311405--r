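#' Indexing parameters
#'
#' @param n consecutive quantized events per seed; `n * (Q - p)` must be
#'   <= 64 so a packed seed fits one machine word before hashing.
#' @param Q,p quantization bits, see [quantizationParams()].
#' @param maskFraction fraction of the most frequent hash buckets masked
#'   out at build time (repetitive-seed masking); 0 disables masking.
#' @return a named list of class `IndexingParams`.
#' @export
indexingParams <- function(n = 6L, Q = 9L, p = 4L, maskFraction = 2e-4) {
  qp <- quantizationParams(Q, p)
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (n * qp$width > 64L) stop("n * (Q - p) must be <= 64 bits")
  if (maskFraction < 0 || maskFraction >= 1)
    stop("maskFraction must be in [0, 1)")
  structure(list(n = n, Q = qp$Q, p = qp$p, width = qp$width,
                 maskFraction = maskFraction), class = "IndexingParams")
}

#' Pack consecutive quantized events into one integer
#'
#' Concatenates the codes MSB-first in event order (earliest event in the
#' highest bits), giving an `n * width`-bit value. Limited to 53 bits here
#' so the result is exact in a double; the internal indexing path packs in
#' a 64-bit word.
#'
#' @param codes integer codes, one per event.
#' @param width bits per code (`Q - p`).
#' @return the packed value as a double.
#' @export
packSeed <- function(codes, width) {
  cpp_pack_seed(as.integer(codes), as.integer(width))[1]
}

#' Hash a packed seed to 32 bits
#'
#' Applies an invertible integer mix (the 32-bit murmur-style finalizer for
#' widths <= 32, a 64-bit mix folded to 32 bits above that), so equal seeds
#' always collide and, for widths <= 32, distinct seeds never do.
#'
#' @param packed non-negative packed seed value(s).
#' @param width total seed width in bits (<= 64).
#' @return hash value(s) in `[0, 2^32)` as doubles.
#' @export
hashSeed <- function(packed, width) {
  cpp_hash_packed(as.numeric(packed), as.integer(width))
}

# per-strand seed extraction for one target; returns hash/pos vectors where
# pos is the forward-coordinate event index of the seed's first event
.target_seeds <- function(seq_chr, model, params) {
  k <- model@k
  zf <- .zscore_or_null(.ref_event_values(seq_chr, model))
  E <- length(zf)
  n <- params$n
  empty <- list(hash = numeric(0), pos = integer(0))
  fwd <- rev <- empty
  if (!is.null(zf) && E >= n) {
    hf <- cpp_seed_hashes(cpp_quantize(zf, params$Q, params$p), n, params$width)
    ok <- which(!is.na(hf))
    fwd <- list(hash = hf[ok], pos = ok - 1L)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_chr)))
  zr <- .zscore_or_null(.ref_event_values(rc, model))
  if (!is.null(zr) && E >= n) {
    hr <- cpp_seed_hashes(cpp_quantize(zr, params$Q, params$p), n, params$width)
    ok <- which(!is.na(hr))
    # seed at reverse-complement event j spans forward events
    # [E - n - j, E - 1 - j]; report the forward leftmost coordinate
    rev <- list(hash = hr[ok], pos = (E - n) - (ok - 1L))
  }
  list(fwd = fwd, rev = rev, events = E)
}

.zscore_or_null <- function(v) {
  ok <- !is.na(v)
  if (sum(ok) < 2L) return(NULL)
  m <- mean(v[ok])
  s <- sqrt(mean((v[ok] - m)^2))
  if (s == 0) return(NULL)
  (v - m) / s
}

#' Build a reference seed index
#'
#' Converts every target sequence (both strands) into normalized expected
#' events, quantizes them, hashes each window of `n` consecutive codes and
#' stores the (target, position, strand) hits in a bucketed hash table.
#' Normalization is per target sequence; reverse-strand seeds are recorded
#' with their positions on the forward coordinate system. Buckets in the
#' top `maskFraction` of occupancy are dropped (repetitive seeds).
#'
#' @param reference FASTA path or a `Biostrings::DNAStringSet`.
#' @param model a [PoreModel-class].
#' @param params an [indexingParams()] list.
#' @return a [ReferenceIndex-class].
#' @export
buildIndex <- function(reference, model, params = indexingParams()) {
  stopifnot(is(model, "PoreModel"))
  ref <- if (is.character(reference)) {
    Biostrings::readDNAStringSet(reference)
  } else reference
  if (length(ref) == 0L) stop("empty reference")
  tnames <- sub("\\s.*$", "", names(ref))
  if (anyDuplicated(tnames)) stop("duplicated target names in reference")
  hashes <- vector("list", length(ref))
  tids <- vector("list", length(ref))
  poss <- vector("list", length(ref))
  strds <- vector("list", length(ref))
  tlen <- integer(length(ref))
  tev <- integer(length(ref))
  for (t in seq_along(ref)) {
    s <- as.character(ref[[t]])
    tlen[t] <- nchar(s)
    sd <- .target_seeds(s, model, params)
    tev[t] <- sd$events
    hashes[[t]] <- c(sd$fwd$hash, sd$rev$hash)
    poss[[t]] <- c(sd$fwd$pos, sd$rev$pos)
    strds[[t]] <- rep(c(1L, -1L), c(length(sd$fwd$pos), length(sd$rev$pos)))
    tids[[t]] <- rep(t, length(poss[[t]]))
  }
  hash <- unlist(hashes, use.names = FALSE)
  tid <- unlist(tids, use.names = FALSE)
  pos <- unlist(poss, use.names = FALSE)
  strd <- unlist(strds, use.names = FALSE)
  if (length(hash) == 0L)
    stop("reference produced no seeds (targets shorter than k + n - 1?)")
  o <- order(hash)
  hash <- hash[o]; tid <- tid[o]; pos <- pos[o]; strd <- strd[o]
  r <- rle(hash)
  keys <- r$values
  sizes <- r$lengths
  masked <- 0
  if (params$maskFraction > 0 && length(keys) > 1L) {
    cut <- stats::quantile(sizes, 1 - params$maskFraction, names = FALSE,
                           type = 1)
    drop <- sizes > cut
    if (any(drop)) {
      masked <- sum(sizes[drop])
      keep_row <- rep(!drop, sizes)
      hash <- hash[keep_row]; tid <- tid[keep_row]
      pos <- pos[keep_row]; strd <- strd[keep_row]
      keys <- keys[!drop]; sizes <- sizes[!drop]
    }
  }
  new("ReferenceIndex", keys = keys,
      bucketStarts = c(1L, cumsum(sizes) + 1L),
      hitTarget = tid, hitPos = pos, hitStrand = strd,
      targetNames = tnames, targetLengths = tlen, targetEvents = tev,
      k = model@k, Q = params$Q, p = params$p, n = params$n,
      maskFraction = params$maskFraction, maskedCount = as.numeric(masked),
      modelId = model@id)
}

#' Query the index with seed hashes
#'
#' Exact-match bucket lookup for each query hash. Hashes whose buckets were
#' masked at build time (or never inserted) return no hits.
#'
#' @param index a [ReferenceIndex-class].
#' @param hashes numeric hash values (NA allowed, yields no hits).
#' @return data.frame with `query` (1-based position in `hashes`), `tid`,
#'   `pos` (forward event coordinate), `strand` (+1/-1).
#' @export
queryIndex <- function(index, hashes) {
  stopifnot(is(index, "ReferenceIndex"))
  hashes <- as.numeric(hashes)
  ki <- findInterval(hashes, index@keys)
  hit <- !is.na(hashes) & ki > 0L
  hit[hit] <- index@keys[ki[hit]] == hashes[hit]
  qi <- which(hit)
  if (length(qi) == 0L)
    return(data.frame(query = integer(0), tid = integer(0),
                      pos = integer(0), strand = integer(0)))
  st <- index@bucketStarts[ki[qi]]
  cnt <- index@bucketStarts[ki[qi] + 1L] - st
  rows <- sequence(cnt) - 1L + rep(st, cnt)
  data.frame(query = rep(qi, cnt), tid = index@hitTarget[rows],
             pos = index@hitPos[rows], strand = index@hitStrand[rows])
}

# ---------------------------------------------------------------------------
# index serialization: little-endian binary container
#   magic "SQGM", version, params, target directory, keys, buckets, hits
# ---------------------------------------------------------------------------

.write_str <- function(con, s) {
  raw <- charToRaw(s)
  writeBin(length(raw), con, size = 4L, endian = "little")
  writeBin(raw, con)
}

.read_str <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  rawToChar(readBin(con, "raw", n))
}

#' Write an index to a binary file
#'
#' Bit-exact little-endian container recording the indexing parameters, the
#' per-target directory and the packed buckets, so that an index built once
#' can be reused across runs and platforms.
#'
#' @param index a [ReferenceIndex-class].
#' @param path output path.
#' @export
writeIndex <- function(index, path) {
  stopifnot(is(index, "ReferenceIndex"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("SQGM"), con)
  writeBin(1L, con, size = 4L, endian = "little")
  writeBin(c(index@k, index@Q, index@p, index@n), con, size = 4L,
           endian = "little")
  writeBin(c(index@maskFraction, index@maskedCount), con, size = 8L,
           endian = "little")
  .write_str(con, index@modelId)
  writeBin(length(index@targetNames), con, size = 4L, endian = "little")
  for (nm in index@targetNames) .write_str(con, nm)
  writeBin(index@targetLengths, con, size = 4L, endian = "little")
  writeBin(index@targetEvents, con, size = 4L, endian = "little")
  writeBin(length(index@keys), con, size = 4L, endian = "little")
  writeBin(index@keys, con, size = 8L, endian = "little")
  writeBin(index@bucketStarts, con, size = 4L, endian = "little")
  writeBin(length(index@hitTarget), con, size = 4L, endian = "little")
  writeBin(index@hitTarget, con, size = 4L, endian = "little")
  writeBin(index@hitPos, con, size = 4L, endian = "little")
  writeBin(index@hitStrand, con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an index written by [writeIndex()]
#'
#' @param path path to the index file.
#' @return a [ReferenceIndex-class].
#' @export
readIndex <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (rawToChar(readBin(con, "raw", 4L)) != "SQGM")
    stop("not a squigglemap index file: ", path)
  ver <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (ver != 1L) stop("unsupported index version: ", ver)
  pp <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  dd <- readBin(con, "numeric", 2L, size = 8L, endian = "little")
  mid <- .read_str(con)
  nt <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  tn <- vapply(seq_len(nt), function(i) .read_str(con), character(1))
  tl <- readBin(con, "integer", nt, size = 4L, endian = "little")
  te <- readBin(con, "integer", nt, size = 4L, endian = "little")
  nk <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  keys <- readBin(con, "numeric", nk, size = 8L, endian = "little")
  bs <- readBin(con, "integer", nk + 1L, size = 4L, endian = "little")
  nh <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  ht <- readBin(con, "integer", nh, size = 4L, endian = "little")
  hp <- readBin(con, "integer", nh, size = 4L, endian = "little")
  hs <- readBin(con, "integer", nh, size = 4L, endian = "little")
  new("ReferenceIndex", keys = keys, bucketStarts = bs, hitTarget = ht,
      hitPos = hp, hitStrand = hs, targetNames = tn, targetLengths = tl,
      targetEvents = te, k = pp[1], Q = pp[2], p = pp[3], n = pp[4],
      maskFraction = dd[1], maskedCount = dd[2], modelId = mid)
}
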