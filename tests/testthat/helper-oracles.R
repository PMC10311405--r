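# Independent oracles used across the suite. Each reimplements the checked
# operation from its definition through a different route than the package.

# 32-character binary string of the single-precision pattern of v
# (via writeBin, big-endian bytes; rawToBits is LSB-first per byte)
float_bits32 <- function(v) {
  if (v == 0) v <- 0 # canonicalize -0
  b <- writeBin(as.numeric(v), raw(), size = 4L, endian = "big")
  s <- integer(32)
  bits <- as.integer(rawToBits(b))
  for (byte in 0:3) s[byte * 8 + 1:8] <- rev(bits[byte * 8 + 1:8])
  paste(s, collapse = "")
}

# reconstruct the double value of a 32-bit pattern given as a binary string
bits32_to_float <- function(s) {
  bits <- as.integer(strsplit(s, "")[[1]])
  stopifnot(length(bits) == 32)
  bytes <- raw(4)
  for (byte in 0:3) {
    bytes[byte + 1] <- packBits(as.raw(rev(bits[byte * 8 + 1:8])), "raw")
  }
  readBin(bytes, "numeric", n = 1L, size = 4L, endian = "big")
}

# string-slicing quantization oracle: code = E[1,2]E[3+p,Q] read as binary
quantize_oracle <- function(v, Q, p) {
  s <- float_bits32(v)
  strtoi(paste0(substr(s, 1, 2), substr(s, 3 + p, Q)), base = 2)
}

# --- 32-bit integer mix reimplemented on 16-bit limbs (doubles are exact
# below 2^53, so each partial product stays exact) ---
.xor32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}
.shr32 <- function(a, k) a %/% 2^k
.mul32 <- function(a, b) {
  ah <- a %/% 65536; al <- a %% 65536
  (al * b + ((ah * b) %% 65536) * 65536) %% 2^32
}
fmix32_oracle <- function(x) {
  h <- x
  h <- .xor32(h, .shr32(h, 16))
  h <- .mul32(h, 2246822507)  # 0x85ebca6b
  h <- .xor32(h, .shr32(h, 13))
  h <- .mul32(h, 3266489909)  # 0xc2b2ae35
  .xor32(h, .shr32(h, 16))
}

# --- Welch t-statistic at 0-based boundary offset i, sample variance ---
welch_t_at <- function(x, i, w) {
  L <- x[(i - w + 1):i]
  R <- x[(i + 1):(i + w)]
  den <- sqrt(stats::var(L) / w + stats::var(R) / w)
  num <- abs(mean(L) - mean(R))
  if (den < 1e-12) return(if (num < 1e-12) 0 else 1e12)
  num / den
}

# --- exhaustive chain search: DFS over every admissible ordered anchor
# subsequence, score = m * match - sum of gap costs ---
chain_bruteforce <- function(a, match_score, gap_scale, max_gap) {
  n <- nrow(a)
  if (n == 0) return(0)
  best <- match_score
  adm <- function(i, j) {
    a$tid[i] == a$tid[j] && a$strand[i] == a$strand[j] &&
      a$cpos[j] > a$cpos[i] && a$qidx[j] > a$qidx[i] &&
      (a$cpos[j] - a$cpos[i]) <= max_gap &&
      (a$qidx[j] - a$qidx[i]) <= max_gap
  }
  rec <- function(last, score) {
    if (score > best) best <<- score
    for (j in seq_len(n)) {
      if (adm(last, j)) {
        gap <- gap_scale * abs((a$cpos[j] - a$cpos[last]) -
                                 (a$qidx[j] - a$qidx[last]))
        rec(j, score + match_score - gap)
      }
    }
  }
  for (s in seq_len(n)) rec(s, match_score)
  best
}

random_anchor_instance <- function(n_anchors, n_targets = 2,
                                   pos_range = 30, q_range = 30) {
  data.frame(
    tid = sample.int(n_targets, n_anchors, replace = TRUE),
    strand = sample(c(1L, -1L), n_anchors, replace = TRUE),
    cpos = sample.int(pos_range, n_anchors, replace = TRUE),
    qidx = sample.int(q_range, n_anchors, replace = TRUE))
}

# --- shared fixtures -------------------------------------------------------
random_reference <- function(n, name = "chr1", seed = NULL) {
  s <- squigglemap:::.with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
  ref <- Biostrings::DNAStringSet(s)
  names(ref) <- name
  ref
}

fixture_model <- function(k = 6) randomPoreModel(k, seed = 7)

paf_fixture <- function(n = 10, seed = 71) {
  squigglemap:::.with_seed(seed, {
    ts <- sample.int(1e6, n)
    data.frame(qname = sprintf("read%02d", 1:n), qlen = 1000L,
               qstart = sample.int(50, n, replace = TRUE) - 1L, qend = 900L,
               strand = sample(c("+", "-"), n, TRUE),
               tname = sample(c("chrA", "chrB"), n, TRUE),
               tlen = 2000000L, tstart = ts, tend = ts + 900L,
               nmatch = sample.int(500, n, replace = TRUE), alen = 900L,
               mapq = 60L, score = round(runif(n, 10, 300), 2),
               chunks_used = sample.int(5, n, replace = TRUE),
               events_used = sample.int(2000, n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}
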