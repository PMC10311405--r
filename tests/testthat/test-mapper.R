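# shared small pipeline fixture: 100 kb reference, default parameters
local_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      model <- fixture_model()
      ref <- random_reference(1e5, seed = 41)
      idx <- buildIndex(ref, model)
      cache <<- list(model = model, ref = ref, idx = idx)
    }
    cache
  }
})

test_that("anchors from a simulated read cluster at the true origin diagonal", {
  px <- local_pipeline()
  sp0 <- simParams(noise_sd = 0, p_stay = 0, p_skip = 0,
                   dwell_dispersion = 0)
  r <- simulateRead(px$ref, px$model, sp0,
                    origin = list(target = "chr1", strand = "+",
                                  start = 30000, length = 900), seed = 1)
  ev <- detectEvents(r$samples)
  z <- normalizeChunkEvents(ev$mean, source = "r")
  anchors <- collectAnchors(z, px$idx)
  diag_hits <- anchors$strand == 1L &
    abs((anchors$pos - anchors$qidx) - 30000) <= px$idx@n + px$idx@k
  expect_gt(sum(diag_hits), 50)
  # determinism: identical events give identical anchors
  expect_identical(collectAnchors(z, px$idx), anchors)
})

test_that("random events produce few anchors and no accepted mapping", {
  px <- local_pipeline()
  set.seed(42)
  z <- rnorm(450)
  z <- (z - mean(z)) / sqrt(mean((z - mean(z))^2))
  anchors <- collectAnchors(z, px$idx)
  chains <- chainAnchors(anchors, px$idx)
  if (nrow(chains) > 0) expect_lt(chains$score[1], chainParams()$min_chain_score)
})

test_that("chaining scores match the exhaustive-search oracle", {
  params <- chainParams(match_score = 1, gap_scale = 0.1, max_gap = 10,
                        max_skip = 1000)
  # single anchor and perfect colinearity
  one <- data.frame(tid = 1L, strand = 1L, cpos = 5L, qidx = 3L)
  expect_equal(chainAnchors(one, local_pipeline()$idx, params)$score, 1)
  m <- 8
  colin <- data.frame(tid = 1L, strand = 1L, cpos = 1:m, qidx = 1:m)
  expect_equal(chainAnchors(colin, local_pipeline()$idx, params)$score[1],
               m * params$match_score)

  set.seed(43)
  for (i in 1:120) {
    a <- random_anchor_instance(sample(2:12, 1))
    a <- a[order(a$tid, a$strand, a$cpos, a$qidx), ]
    dp <- max(squigglemap:::cpp_chain_scores(
      a$tid, a$strand, a$cpos, a$qidx, params$match_score,
      params$gap_scale, params$max_gap, params$max_skip))
    bf <- chain_bruteforce(a, params$match_score, params$gap_scale,
                           params$max_gap)
    expect_equal(dp, bf, tolerance = 1e-9)
  }
})

test_that("adding an anchor never decreases the best chain score", {
  params <- chainParams(match_score = 1, gap_scale = 0.1, max_gap = 10,
                        max_skip = 1000)
  best_of <- function(a) {
    max(squigglemap:::cpp_chain_scores(a$tid, a$strand, a$cpos, a$qidx,
                                       params$match_score, params$gap_scale,
                                       params$max_gap, params$max_skip))
  }
  set.seed(44)
  for (i in 1:50) {
    a <- random_anchor_instance(sample(3:10, 1))
    o <- order(a$tid, a$strand, a$cpos, a$qidx)
    a <- a[o, ]
    s1 <- best_of(a)
    extra <- random_anchor_instance(1)
    a2 <- rbind(a, extra)
    a2 <- a2[order(a2$tid, a2$strand, a2$cpos, a2$qidx), ]
    expect_gte(best_of(a2), s1 - 1e-12)
  }
})

test_that("streaming mapping recovers the origin of simulated reads", {
  px <- local_pipeline()
  sp0 <- simParams(noise_sd = 0, p_stay = 0, p_skip = 0,
                   dwell_dispersion = 0)
  for (st in c("+", "-")) {
    r <- simulateRead(px$ref, px$model, sp0,
                      origin = list(target = "chr1", strand = st,
                                    start = 60000, length = 1200), seed = 2)
    m <- mapSignal(r$samples, px$idx, read_id = "r")
    expect_true(m$mapped)
    expect_equal(m$strand, st)
    expect_equal(m$chunks_used, 1L)
    slack <- px$idx@n + px$idx@k
    if (st == "+") {
      expect_lte(abs((m$tstart - m$qstart) - 60000), slack)
    } else {
      expect_lte(abs((m$tend + m$qstart) - 61200), slack)
    }
  }
})

test_that("reads from an unindexed genome stay unmapped after max_chunks", {
  px <- local_pipeline()
  other <- random_reference(20000, name = "alien", seed = 45)
  r <- simulateRead(other, px$model, simParams(),
                    origin = list(target = "alien", strand = "+",
                                  start = 2000, length = 9000), seed = 3)
  params <- chainParams(max_chunks = 3)
  m <- mapSignal(r$samples, px$idx, params = params, read_id = "r")
  expect_false(m$mapped)
  expect_equal(m$chunks_used, 3L)
})

test_that("an exactly duplicated region defers acceptance (ratio test)", {
  model <- fixture_model()
  set.seed(46)
  block <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                 collapse = "")
  flank <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
  ref <- Biostrings::DNAStringSet(paste0(flank(5000), block, flank(5000),
                                         block, flank(5000)))
  names(ref) <- "dup"
  idx <- buildIndex(ref, model)
  sp0 <- simParams(noise_sd = 0, p_stay = 0, p_skip = 0,
                   dwell_dispersion = 0)
  # read fully inside the first copy of the duplicated block
  r <- simulateRead(ref, model, sp0,
                    origin = list(target = "dup", strand = "+",
                                  start = 5600, length = 1500), seed = 4)
  m <- mapSignal(r$samples, idx, read_id = "r")
  expect_false(m$mapped)
})

test_that("chunked and single-pass mapping agree when both accept", {
  px <- local_pipeline()
  sp0 <- simParams(noise_sd = 0, p_stay = 0, p_skip = 0,
                   dwell_dispersion = 0)
  r <- simulateRead(px$ref, px$model, sp0,
                    origin = list(target = "chr1", strand = "+",
                                  start = 25000, length = 2000), seed = 5)
  m1 <- mapSignal(r$samples, px$idx, read_id = "r", chunk_seconds = 1)
  m2 <- mapSignal(r$samples, px$idx, read_id = "r",
                  chunk_seconds = 1e6) # whole read in one pass
  expect_true(m1$mapped && m2$mapped)
  expect_equal(m1$target, m2$target)
  expect_equal(m1$strand, m2$strand)
  expect_lte(abs((m1$tstart - m1$qstart) - (m2$tstart - m2$qstart)), 50)
})

test_that("degenerate inputs give clean unmapped records", {
  px <- local_pipeline()
  m <- mapSignal(numeric(0), px$idx, read_id = "empty")
  expect_false(m$mapped)
  expect_equal(m$chunks_used, 0L)
  m2 <- mapSignal(rep(90, 50), px$idx, read_id = "tiny")
  expect_false(m2$mapped)
})
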