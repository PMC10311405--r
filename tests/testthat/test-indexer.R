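test_that("seed packing concatenates codes MSB-first in event order", {
  expect_equal(packSeed(5L, 4), 5)          # n = 1 is the identity
  expect_equal(packSeed(c(3L, 5L), 4), 53) # 0011 ++ 0101 = 00110101b = 53
  expect_false(packSeed(c(3L, 5L), 4) == packSeed(c(5L, 3L), 4))
  expect_error(packSeed(c(16L, 1L), 4), "width")
})

test_that("the 32-bit mix is injective, deterministic and matches its oracle", {
  h <- hashSeed(0:1023, 10)
  expect_length(unique(h), 1024L) # bijection on a 10-bit domain
  expect_identical(hashSeed(0:1023, 10), h)
  expect_true(all(h >= 0 & h < 2^32))
  # oracle: 16-bit-limb reimplementation of the mix constants
  set.seed(21)
  vals <- c(0, 1, 12345, floor(runif(50) * 2^30))
  expect_equal(hashSeed(vals, 30),
               vapply(vals, fmix32_oracle, numeric(1)))
  # above 32 bits collisions become possible but stay near the birthday bound
  set.seed(22)
  big <- unique(floor(runif(1e5) * 2^40))
  expect_lte(length(big) - length(unique(hashSeed(big, 40))), 5L)
})

test_that("buildIndex stores re-verifiable hits for every window", {
  model <- loadPoreModel(system.file("extdata", "pore_model_k3_synthetic.txt",
                                     package = "squigglemap"))
  params <- indexingParams(n = 4, Q = 9, p = 4, maskFraction = 0)
  ref <- random_reference(2000, seed = 31)
  idx <- buildIndex(ref, model, params)

  # oracle: full recomputation through the R-level primitives
  z <- eventValues(normalizeEvents(seqToEvents(as.character(ref[[1]]), model)))
  codes <- quantizeEvents(z, quantizationParams(9, 4))
  E <- length(z)
  fwd <- idx@hitStrand == 1L
  expect_equal(sum(fwd), E - params$n + 1L)
  sel <- sample(which(fwd), 50)
  for (i in sel) {
    pos <- idx@hitPos[i]
    h <- hashSeed(packSeed(codes[(pos + 1):(pos + params$n)], 5), 20)
    bucket <- findInterval(h, idx@keys)
    expect_equal(idx@keys[bucket], h)
    rows <- idx@bucketStarts[bucket]:(idx@bucketStarts[bucket + 1] - 1)
    expect_true(any(idx@hitPos[rows] == pos & idx@hitTarget[rows] == 1L &
                      idx@hitStrand[rows] == 1L))
  }
})

test_that("a target of exactly n + k - 1 bases yields one forward seed", {
  model <- loadPoreModel(system.file("extdata", "pore_model_k3_synthetic.txt",
                                     package = "squigglemap"))
  params <- indexingParams(n = 6, maskFraction = 0)
  ref <- random_reference(6 + 3 - 1, seed = 32)
  idx <- buildIndex(ref, model, params)
  expect_equal(sum(idx@hitStrand == 1L), 1L)
  expect_equal(idx@hitPos[idx@hitStrand == 1L], 0L)
})

test_that("identical targets share hashes; queries hit recorded positions", {
  model <- fixture_model()
  params <- indexingParams(maskFraction = 0)
  s <- random_reference(400, seed = 33)
  ref2 <- Biostrings::DNAStringSet(c(as.character(s[[1]]),
                                     as.character(s[[1]])))
  names(ref2) <- c("a", "b")
  idx <- buildIndex(ref2, model, params)
  h_a <- idx@hitTarget == 1L
  h_b <- idx@hitTarget == 2L
  # same seed content => per-position hits mirrored on both target ids
  expect_equal(sum(h_a), sum(h_b))
  o_a <- order(idx@hitStrand[h_a], idx@hitPos[h_a])
  o_b <- order(idx@hitStrand[h_b], idx@hitPos[h_b])
  expect_equal(idx@hitPos[h_a][o_a], idx@hitPos[h_b][o_b])

  # query a hash never inserted -> empty
  absent <- 0
  while (absent %in% idx@keys) absent <- absent + 1
  expect_equal(nrow(queryIndex(idx, absent)), 0L)

  # a seed present once per copy -> hits at both recorded positions
  k1 <- idx@keys[which(diff(idx@bucketStarts) == 2L)[1]]
  hits <- queryIndex(idx, k1)
  expect_equal(nrow(hits), 2L)
  expect_setequal(hits$tid, 1:2)
})

test_that("every reference position retrieves itself (self-mapping completeness)", {
  model <- fixture_model()
  params <- indexingParams(maskFraction = 0)
  ref <- random_reference(800, seed = 34)
  idx <- buildIndex(ref, model, params)
  z <- eventValues(normalizeEvents(seqToEvents(as.character(ref[[1]]), model)))
  codes <- quantizeEvents(z, quantizationParams(idx@Q, idx@p))
  h <- squigglemap:::cpp_seed_hashes(codes, idx@n, idx@Q - idx@p)
  hits <- queryIndex(idx, h)
  self <- hits$strand == 1L & hits$pos == hits$query - 1L
  expect_setequal(hits$query[self], seq_along(h))
})

test_that("index files round-trip bit-exactly", {
  model <- loadPoreModel(system.file("extdata", "pore_model_k3_synthetic.txt",
                                     package = "squigglemap"))
  ref <- random_reference(500, name = "contig_1", seed = 35)
  idx <- buildIndex(ref, model, indexingParams(n = 5))
  f <- withr::local_tempfile(fileext = ".idx")
  writeIndex(idx, f)
  idx2 <- readIndex(f)
  for (sl in slotNames(idx)) {
    expect_identical(slot(idx2, sl), slot(idx, sl), label = sl)
  }
  expect_error(readIndex(system.file("extdata",
                                     "pore_model_k3_synthetic.txt",
                                     package = "squigglemap")), "index")
})

test_that("repetitive-seed masking drops only the hottest buckets", {
  model <- fixture_model()
  ref <- random_reference(20000, seed = 36)
  idx0 <- buildIndex(ref, model, indexingParams(maskFraction = 0))
  idx1 <- buildIndex(ref, model, indexingParams(maskFraction = 0.01))
  expect_gt(idx1@maskedCount, 0)
  expect_equal(length(idx0@hitTarget) - length(idx1@hitTarget),
               idx1@maskedCount)
  # the surviving max bucket is no larger than the smallest masked one
  s0 <- diff(idx0@bucketStarts)
  s1 <- diff(idx1@bucketStarts)
  expect_lte(max(s1), min(s0[!(idx0@keys %in% idx1@keys)]))
})
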