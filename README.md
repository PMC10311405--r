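# squigglemap

Real-time mapping of raw nanopore current signals to a reference genome,
without basecalling.

Nanopore sequencers emit their raw electrical signal while each strand is
still translocating (~450 bases/s), and they can eject a strand on command
(Read Until) or stop the whole run (Run Until). Deciding *during*
sequencing where a read comes from therefore saves pore time and cost —
but only if the decision keeps up with the pore on modest hardware.
squigglemap is for people building or studying such adaptive-sampling
pipelines: it maps squiggles by hashing, streams its decisions chunk by
chunk, monitors relative abundance in real time, and ships a ground-truthed
signal simulator so everything can be developed and tested offline.

## The mechanism

Both sides of the comparison are turned into *events* — mean currents of
segments that each correspond to one k-mer:

* **Reference:** each k-mer's expected level from a pore model, z-scored
  per contig.
* **Read:** raw samples segmented by multi-window Welch t-tests, one mean
  per segment, z-scored per one-second chunk.

A normalized event value `E` is quantized to the bit slice
`E[1,2] E[3+p, Q]` of its IEEE-754 single-precision pattern (defaults
`Q = 9`, `p = 4`: 5-bit codes), so nearby values deliberately collide.
`n = 6` consecutive codes are packed MSB-first into `n(Q-p)` bits and
mixed to a 32-bit hash; a hash table over both strands of the reference
makes seed lookup O(1). Matches are assembled by colinear chaining with

    f(j) = match + max(0, max_i f(i) - gamma |dT - dQ|)

(no anchor-distance coefficient), and a read is accepted once its best
chain passes a score floor and beats the best competing region by a
ratio — the unconsumed signal is then dropped, emulating Read Until. For
community references, mapped-read proportions are re-estimated every
`n` reads; when the last `w` estimates contain no cross-correlation
outlier, the run stops (Sequence Until).

## Worked example

```r
library(squigglemap)
library(Biostrings)

model <- randomPoreModel(6, seed = 7)           # synthetic 6-mer pore model
set.seed(42)
ref <- DNAStringSet(paste(sample(c("A","C","G","T"), 2e5, replace = TRUE),
                          collapse = ""))
names(ref) <- "chr1"

index <- buildIndex(ref, model)
index
#> ReferenceIndex: 1 targets, 399,366 hits in 301,228 buckets
#>   k = 6, Q = 9, p = 4, n = 6 (seed width 30 bits)
#>   model 'synthetic_k6_seed7'; 614 hits masked (top 0.02% buckets)

sim <- simulateRun(ref, model, 50, simParams(), seed = 11)  # noisy reads
maps <- mapReads(sim$reads, index)
maps[1:3, c("read_id","mapped","target","strand","tstart","tend","score","chunks_used")]
#>      read_id mapped target strand tstart   tend  score chunks_used
#> 1 sim_read_1   TRUE   chr1      + 197528 197976 196.68           1
#> 2 sim_read_2   TRUE   chr1      + 102859 103283  25.81           1
#> 3 sim_read_3   TRUE   chr1      -  92964  93408 109.81           1

compareToTruth(mappingsToPaf(maps, index), sim$truth, tolerance = 100)
#> TP=50 FP=0 FN=0  P=1.0000 R=1.0000 F1=1.0000
```

Every read here was placed from its first one-second chunk
(`chunks_used = 1`, i.e. ~450 bases of a longer read), on the correct
strand, within 100 bases of its true origin; `score` is the chain score
(≈ number of chained seed matches), and the precision/recall/F1 line is
the pafstats-style comparison against the simulator's ground truth.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/squigglemap.R index    -r ref.fa -m model.txt -o ref.idx
Rscript inst/cli/squigglemap.R simulate -r ref.fa -m model.txt -n 1000 --seed 7 \
                                        -o reads.signals --truth truth.paf
Rscript inst/cli/squigglemap.R map      -i ref.idx -s reads.signals -o out.paf
Rscript inst/cli/squigglemap.R abundance -i ref.idx -s reads.signals \
                                        --sequence-until -o abundance.tsv
```

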