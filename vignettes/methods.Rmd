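---
title: "Mapping raw nanopore signals by quantized event hashing: methods and design notes"
author: "squigglemap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping raw nanopore signals by quantized event hashing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

A nanopore sequencer reports the ionic current through each pore in real
time, thousands of samples per second, while the DNA strand it is reading
translocates at roughly 450 bases per second. If the software can decide
*while a read is still in the pore* where that read comes from, the
sequencer can eject it (Read Until) or stop the whole run (Run Until),
saving pore time and reagent. Basecalling-then-mapping is too expensive for
this on portable hardware, so squigglemap matches the raw signal itself
against a reference genome.

The central obstacle is that two sequencings of the same DNA never produce
identical currents. The pipeline therefore converts both sides into a
representation that is deliberately insensitive to small amplitude
differences, and insists on *colinear runs* of matches rather than single
matches.

# The pipeline

## Reference side: expected events

A pore reads k bases at a time (k = 6 for the chemistries this package
emulates), and each segment of near-constant current — an *event* —
corresponds to one k-mer. A *pore model* maps every k-mer to its expected
mean current. `seqToEvents()` slides over a contig and emits one expected
event value per k-mer position; `normalizeEvents()` z-scores them per
contig (population standard deviation). Normalization is what makes the
units of the model irrelevant and the two sides comparable.

K-mers containing ambiguous bases produce no event but keep their
position, so no levels are invented and coordinates stay absolute.
Lowercase (soft-masked) bases count as their uppercase base.

## Signal side: segmentation into events

`detectBoundaries()` computes Welch's t-statistic between the two adjacent
rolling windows at every sample offset and calls a boundary where the
statistic exceeds a threshold and is a local peak. Two window lengths are
combined (union of the boundary sets) so that both short and long dwells
are caught despite the varying translocation speed (skip/stay errors).
Each segment becomes one event, summarized by its mean
(`segmentsToEvents()`); segments shorter than `min_len` samples are
discarded as stay/spike artifacts.

Three numerical details matter:

* **Degeneracy guard.** Variances are computed from prefix sums; in an
  exactly constant run, cancellation leaves a residue of order
  `eps * |signal|` instead of zero. The zero-variance test is therefore
  scaled to the window means; without this, noise-free signals sprout
  spurious "infinite-t" boundaries.
* **Non-maximum suppression.** Within one window track, a peak closer
  than the window length to a stronger peak is a side lobe of the same
  level transition and is dropped.
* **Streaming.** The mapper consumes signal in chunks (default one second,
  `sample_rate` samples). The unterminated tail segment after the last
  boundary of a chunk is carried into the next chunk, so boundaries that
  straddle chunk edges are not lost.

Events of one chunk are z-scored together (`normalizeChunkEvents()`), the
same transform as the reference side. One second of signal holds roughly
450 events, enough for stable chunk statistics; a chunk with fewer than
two events is merged into the next one.

Default segmentation parameters are windows of 3 and 6 samples with
t-thresholds 4.3 and 2.57 and `min_len` 3. They are calibrated so that a
noise-free simulated read segments into exactly one event per k-mer step
(the round-trip tests exercise this), and they are all exposed in
`segmentationParams()`.

## Quantization

Normalized event values from the same k-mer are close but not equal, so
exact matching needs a code under which close values collide.
`quantizeEvents()` takes the value's IEEE-754 single-precision pattern,
keeps the most significant `Q` bits, and prunes `p` bits immediately after
the top two (sign and exponent MSB), leaving a `Q - p`-bit code
`E[1,2]E[3+p,Q]` (bit 1 = most significant; negative zero is canonicalized
first). Since z-scored values live mostly in [-3, 3], the pruned exponent
bits carry almost no information; the retained bits bucket values roughly
by sign and octave with a few fraction bits of refinement. The defaults
`Q = 9, p = 4` give 5-bit codes.

The price of coarse buckets is octave-boundary sensitivity (0.99 and 1.01
quantize differently) and a rare aliasing of very small magnitudes with
larger ones; both are tolerated because a mapping decision never rests on
one code but on a chained run of seed matches.

## Seeds, hashing and the index

A single event (one k-mer) occurs far too often in a genome to be a
useful query, so `n` consecutive codes (default 6, spanning 11 bases) are
packed MSB-first — earliest event in the highest bits — into
`n * (Q - p)` bits and mixed into a 32-bit hash (`packSeed()`,
`hashSeed()`). For packed widths up to 32 bits the mix (a murmur-style
finalizer) is a bijection, so distinct seeds never collide; above 32 bits
a 64-bit mix is folded and rare collisions are left to chaining to reject.

`buildIndex()` runs the reference pipeline on both strands of every
target, storing hits keyed by hash. Reverse-strand seeds are computed on
the reverse complement and recorded in forward coordinates with a strand
flag, and both reference and reads are quantized with the same `(Q, p)` —
the index stores its parameters and the query side always derives them
from the index, so a parameter mismatch cannot arise by construction.
Buckets in the top 0.02% of occupancy (repetitive seeds) are masked at
build time, bounding chaining cost on repeats. `writeIndex()` /
`readIndex()` serialize the table to a little-endian binary container that
round-trips bit-exactly.

## Chaining and the mapping decision

Each query-seed hit becomes an anchor (read window, reference position,
strand). Chaining maximizes, by dynamic programming over anchors sorted by
position,

    f(j) = match + max(0, max_i f(i) - gamma * |dT - dQ|)

over admissible predecessors: same target and strand, both coordinates
strictly increasing, both deltas bounded by `max_gap`. The gap cost uses
only the diagonal drift `|dT - dQ|` — there is no per-anchor distance
coefficient — so a skipped or merged event costs almost nothing while a
dislocated anchor is heavily penalized. Reverse-strand anchors are chained
in a mirrored coordinate so that both strands run through the same DP.
Look-back is truncated at `max_skip` predecessors; the oracle-equivalence
tests disable the truncation and check the DP against exhaustive search.

After each chunk the mapper re-chains the cumulative anchor set and
accepts when the best chain reaches `min_chain_score` (default 15) **and**
outscores the best chain from any other region by `best_ratio` (default
1.2); a competing region is one on a different target or strand, or
overlapping the best by less than half. The ratio test is what defers
reads from duplicated regions instead of placing them arbitrarily. On
acceptance the remaining signal is not consumed — the Read Until
surrogate; after `max_chunks` chunks (default 10) the read is reported
unmapped. Per-chunk decisions, not the chain recurrence, are where the
streaming behavior lives: an unsuccessful chunk simply transfers its
anchors forward.

Coordinates are reported PAF-style, 0-based half-open, with one event
standing in for one base on the query side (each event advances the pore
by one base) and the k-mer span added at the target end. Ties between
equal-scoring chains break deterministically (lexicographic target, then
start).

## Relative abundance and Sequence Until

When the reference is a community of genomes (record ids carrying a
`taxid|<id>|` prefix), every accepted mapping increments its taxon's
count. After every `estimate_every` mapped reads (default 500) the
proportions *over that interval* are appended to a history of the last
`window_w` estimates (default 5). The run has converged when no estimate
in the window is an outlier: each vector is compared to the mean of the
other `w - 1` by uncentered normalized cross-correlation (cosine
similarity), and an estimate is an outlier below `outlier_threshold`
(default 0.99). At convergence the whole run stops and the cumulative
proportions are reported.

Two design choices deserve their rationale:

* **Cosine, not Pearson.** Composition vectors over two taxa are
  degenerate under Pearson correlation (always exactly ±1 after
  centering), which would declare any two-taxon drift converged. The
  uncentered correlation has no such degeneracy, handles the single-taxon
  case, and preserves the intended behavior: identical windows converge,
  an orthogonal outlier blocks, a window-wide drift blocks.
* **Interval estimates, not cumulative.** Successive cumulative estimates
  share almost all their counts, so their correlation approaches 1 no
  matter how the underlying mixture is moving; windowed estimates make
  drift visible while 500-read intervals keep multinomial noise well
  above the threshold for stationary streams. The reported estimate is
  still the cumulative one, which is the lower-variance summary.

With the defaults, a stationary 5-taxon stream of 50 000 mapped reads
stops after a few thousand reads with per-taxon error well under 0.05,
while a stream whose mixture is still drifting does not stop — both are
pinned down in the acceptance tests.

# The simulator

`simulateRead()` inverts the reference pipeline to produce raw-like
signals with ground truth: draw an origin (length-weighted across targets,
both strands), walk the traversed k-mers, and emit for each one a dwell of
`sample_rate / bases_per_second` samples (default 4000/450 ≈ 8.9) jittered
by a dispersion factor, at the pore-model level plus Gaussian noise.
K-mers are independently dropped (skip) or given a doubled dwell (stay).
`simulateRun()` draws each read's taxon i.i.d. from a mixture, giving the
randomly interleaved arrival order of a real pooled run, and writes a
plain-text signal file plus a ground-truth PAF.

Defaults — noise sd 0.25 in model-level units, stay and skip probabilities
0.05, dwell dispersion 0.3 — are the study conditions of the test suite:
strong enough that segmentation and quantization errors actually occur,
mild enough that a correct pipeline recovers ≥ 95% of origins. What the
simulator does *not* emulate: adapter/stall regions at read starts,
per-pore calibration drift within a read, ADC quantization, RNA kinetics,
and level correlation between overlapping k-mers (model levels are drawn
i.i.d., which makes neighboring events less correlated than in a real
pore). Passing the suite therefore demonstrates the mechanism's internal
consistency and its robustness to the modeled error processes, not
calibrated accuracy on any particular chemistry.

The pore models used throughout are synthetic (`randomPoreModel()`,
levels i.i.d. normal, mean 90 pA, sd 10 pA — the scale of published 6-mer
tables); `loadPoreModel()` reads ONT-style `kmer / level_mean` tables when
a real chemistry is wanted.

# Evaluation conventions

`compareToTruth()` follows pafstats-style accounting: truth-unmapped reads
are excluded; per truth-mapped read the primary call is a true positive
when target and strand agree and the mapping position is within a
tolerance (default 500 bases; the end-to-end tests use 100). Because a
streaming mapper covers only the consumed prefix and its chain may start
events into the read, the distance projects the call back to the read
origin using the query start (`tstart - qstart` forward, `tend + qstart`
reverse). Precision, recall and F1 follow the standard definitions
`TP/(TP+FP)`, `TP/(TP+FN)`, `2PR/(P+R)`. Abundance estimates are compared
by Euclidean distance.

# Problem sizes and determinism

The test suite and `scripts/acceptance.R` run entirely on simulated data:
a 1 Mb random reference with 500 reads for end-to-end recovery (noisy and
noise-free variants), a 5 × 120 kb community with 400 reads for abundance,
a 50 000-record mapping stream for Sequence Until, 1000 random anchor
instances for the chaining oracle, and 10^5 sampled values for the
quantization laws. These sizes make every stage's statistics stable while
a full run stays in the tens of seconds. All randomness flows through
explicit seeds; the acceptance script derives one sub-seed per stage from
its `--seed` argument, and fixed seeds make the simulator byte-identical
across runs.

# Known limitations

* Event counts stand in for base counts in query coordinates; with skips
  and merged events the implied read position can drift by a few bases
  per hundred, which is inside the evaluation tolerance but not exact.
* The quantization is scale-coupled: chunk normalization must land close
  to the contig normalization, so chunks much shorter than a few hundred
  events (very short reads, sparse signals) match poorly.
* Repetitive genomes are handled by masking and the best/second-best
  ratio, not resolved; reads from exact repeats are deliberately left
  unmapped.
* The index keeps all seeds of both strands in memory; minimizer-style
  seed sampling would shrink it and is intentionally out of scope here.
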