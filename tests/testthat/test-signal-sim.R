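test_that("noise-free simulation emits the model levels in k-mer order", {
  model <- loadPoreModel(system.file("extdata", "pore_model_k3_synthetic.txt",
                                     package = "squigglemap"))
  ref <- Biostrings::DNAStringSet("ACGTTGCAAC")
  names(ref) <- "t"
  sp0 <- simParams(noise_sd = 0, p_stay = 0, p_skip = 0,
                   dwell_dispersion = 0)
  r <- simulateRead(ref, model, sp0,
                    origin = list(target = "t", strand = "+", start = 0,
                                  length = 10), seed = 1)
  lv <- rle(r$samples)$values
  kmers <- substring("ACGTTGCAAC", 1:8, 3:10)
  expect_equal(lv, unname(levelMeans(model)[kmers]))
  # dwell is uniform at round(sample_rate / bases_per_second)
  expect_true(all(rle(r$samples)$lengths == round(4000 / 450)))
  # reverse strand walks the reverse complement
  r2 <- simulateRead(ref, model, sp0,
                     origin = list(target = "t", strand = "-", start = 0,
                                   length = 10), seed = 1)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ACGTTGCAAC")))
  expect_equal(rle(r2$samples)$values,
               unname(levelMeans(model)[substring(rc, 1:8, 3:10)]))
})

test_that("simulation is deterministic under a fixed seed", {
  model <- fixture_model()
  ref <- random_reference(5000, seed = 51)
  r1 <- simulateRead(ref, model, simParams(), seed = 99)
  r2 <- simulateRead(ref, model, simParams(), seed = 99)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$truth, r2$truth)
  s1 <- simulateRun(ref, model, 5, simParams(), seed = 123)
  s2 <- simulateRun(ref, model, 5, simParams(), seed = 123)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$reads[[3]]$samples, s2$reads[[3]]$samples)
})

test_that("skip errors drop k-mers at the binomial rate", {
  model <- fixture_model()
  ref <- random_reference(12000, seed = 52)
  sp <- simParams(noise_sd = 0, p_stay = 0, p_skip = 0.05,
                  dwell_dispersion = 0)
  r <- simulateRead(ref, model, sp,
                    origin = list(target = "chr1", strand = "+", start = 0,
                                  length = 10005), seed = 6)
  n <- 10000 # k-mers walked
  expect_lt(abs(r$n_kmers - n * 0.95), 3 * sqrt(n * 0.95 * 0.05))
})

test_that("simulated runs follow the requested mixture with valid truth", {
  model <- fixture_model()
  set.seed(53)
  mk <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  ref <- Biostrings::DNAStringSet(c(mk(30000), mk(30000)))
  names(ref) <- c("taxid|tx_a|genome1", "taxid|tx_b|genome2")
  sp <- simParams(read_length_mean = 600, read_length_sd = 100,
                  read_length_min = 150)

  one <- simulateRun(ref, model, 30, sp, mixture = c(tx_a = 1.0), seed = 7)
  expect_true(all(one$truth$tname == "taxid|tx_a|genome1"))

  run <- simulateRun(ref, model, 2000, sp,
                     mixture = c(tx_a = 0.5, tx_b = 0.5), seed = 8)
  n_a <- sum(run$truth$tname == "taxid|tx_a|genome1")
  expect_lt(abs(n_a - 1000), 3 * sqrt(2000 * 0.25))
  # truth intervals inside their targets
  expect_true(all(run$truth$tstart >= 0 &
                    run$truth$tend <= run$truth$tlen))
  expect_error(simulateRun(ref, model, 5, sp, mixture = c(tx_a = 0.7)),
               "sum to 1")
})

test_that("signal text files round-trip", {
  model <- fixture_model()
  ref <- random_reference(4000, seed = 54)
  run <- simulateRun(ref, model, 3,
                     simParams(read_length_mean = 400,
                               read_length_sd = 50,
                               read_length_min = 200), seed = 9)
  f <- withr::local_tempfile(fileext = ".signals")
  writeSignals(run$reads, f)
  back <- readSignals(f)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$read_id, run$reads[[i]]$read_id)
    expect_equal(back[[i]]$sample_rate, run$reads[[i]]$sample_rate)
    expect_equal(back[[i]]$samples, run$reads[[i]]$samples,
                 tolerance = 1e-4)
  }
  writeLines(c("only_two\tfields"), f)
  expect_error(readSignals(f), "line 1")
})

test_that("noise-free events round-trip to the reference's own normalized events", {
  model <- fixture_model()
  ref <- random_reference(8000, seed = 57)
  sp0 <- simParams(noise_sd = 0, p_stay = 0, p_skip = 0,
                   dwell_dispersion = 0)
  r <- simulateRead(ref, model, sp0,
                    origin = list(target = "chr1", strand = "+",
                                  start = 3000, length = 1200), seed = 10)
  ev <- detectEvents(r$samples)
  # oracle: the origin's expected events, normalized over the same window
  sub <- substr(as.character(ref[[1]]), 3001, 3000 + 1200)
  want <- eventValues(normalizeEvents(seqToEvents(sub, model)))
  expect_equal(nrow(ev), length(want))
  got <- eventValues(normalizeChunkEvents(ev$mean))
  expect_equal(got, want, tolerance = 1e-6)
})

test_that("infeasible origins are rejected", {
  model <- fixture_model()
  ref <- random_reference(1000, seed = 55)
  expect_error(simulateRead(ref, model, simParams(),
                            origin = list(target = "chr1", strand = "+",
                                          start = 900, length = 500)),
               "infeasible|bounds")
  expect_error(simulateRead(ref, model, simParams(),
                            origin = list(target = "nope", strand = "+",
                                          start = 0, length = 100)),
               "target")
})
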