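# anchorchain

Minimizer seeding and anchor chaining for long noisy reads, with two
interchangeable chaining engines: the classic sequential predecessor-order
dynamic program and a **forward-transformed** successor-order DP that produces
bit-identical results while removing the sequential dependency that makes
classic chaining hard to parallelize.

## The problem and who this is for

Long-read mappers follow the seed-chain-align paradigm. *Seeding* finds short
exact matches (anchors) between a read and a reference through a minimizer
hash index; *chaining* runs a 1-D dynamic program over the position-sorted
anchors to select collinear ordered subsets (chains), so that base-level
alignment only has to close small gaps inside a few candidate regions. For
noisy nanopore reads, chaining dominates mapping time, and its textbook
formulation is inherently sequential: each anchor scans up to 5,000
predecessors backwards and keeps the best.

This package is for people studying or engineering that chaining stage: it
provides the exact sequential DP (with the MAX_SKIP early-exit heuristic
either active or disabled), the forward transformation of it, and the
differential-testing machinery to show the two are *integer-identical* —
plus enough seeding, backtracking, classification and PAF output to run the
whole pipeline end to end on real or simulated FASTA.

## The algorithm

For anchors sorted by reference position, with query gap `dq = y_j − y_i`,
reference gap `dr = x_j − x_i`, and gap difference `dd = |dq − dr|`, a pair
is chainable when `0 < dq ≤ G`, `0 < dr ≤ G` (gap limit `G` = 5000) and
`dd ≤ B` (bandwidth 500), scoring

```
score(i, j) = min(dq, dr, w_j) − ⌊0.01 · w̄ · dd⌋ − ⌊log2 dd⌋/2
```

(all integer; `w̄` is the mean anchor span). The DP is
`S[j] = max(w_j, max_i S[i] + score(i, j))`, with `P[j]` the best
predecessor and `V[j] = max(S[j], V[P[j]])` the running chain maximum.

* `chain_backward()` — for each `j`, scan `i = j−1` down to the range start,
  update on strict improvement (nearest predecessor wins ties). Finite
  `max_skip` reproduces the early-exit speed heuristic; `max_skip = Inf`
  (the default) is the exact DP.
* `chain_forward()` — each anchor `i`, in ascending order, *pushes*
  `S[i] + score(i, j)` to every `j` in its successor range, updating on
  `s > S[j]`, or `s == S[j]` provided `S[j]` is not still the anchor's own
  span. All pushes from one source are independent; the result is
  bit-identical to the exact backward DP, including tie-breaks.
* `successor_ranges()` — finds each anchor's successor run by probing the
  offsets {0, 16, 512, 1024, 2048, 3072, 4096, 5000} and decrementing to the
  exact boundary: equal to a linear scan, in far fewer iterations.
  `condense()` drops the (many) anchors with empty ranges; chaining over the
  condensed workload is provably lossless.
* `backtrack()`, `identify_primary()`, `mapping_quality()` — chain
  extraction with a no-anchor-reuse guarantee, query-overlap masking of
  secondaries, and the empirical mapq formula
  `40 (1 − f2/f1) min(1, m/10) ln f1`, clamped to [0, 60].
* `map_reads()` — FASTA in, PAF out; `engine = "both"` chains every read
  with both engines and aborts on the first differing PAF field.

Synthetic-data generators (`plant_chains()`, `simulate_read()`,
`sample_read_lengths()`, `random_reference()`) make the whole test suite
self-contained.

## A worked example

```r
library(anchorchain)
p <- map_params()   # ONT-style defaults: k=15, w=10, gaps<=5000, bandwidth 500

ref   <- c(chr1 = random_reference(50000, seed = 5))
reads <- c(r1 = substr(ref[[1]], 10001, 18000),            # forward copy
           r2 = revcomp(substr(ref[[1]], 30001, 34000)))   # reverse strand
paf <- map_reads(ref, reads, p, engine = "both")           # engines must agree
paf[paf$tp, c("qname","qlen","qstart","qend","strand","tname","tstart","tend","nmatch","mapq")]
#>  qname qlen qstart qend strand tname tstart  tend nmatch mapq
#>     r2 4000      0 3995      -  chr1  30005 34000   3995   60
#>     r1 8000      7 7998      +  chr1  10007 17998   7991   60
```

Each read returns one primary chain at its true window (`r1` was cut from
positions 10000-18000, `r2` is the reverse complement of 30000-34000), on the
correct strand, with `nmatch` the summed anchor spans and mapq 60 (no
competing placement). The few bases shaved at the interval edges are the
half-window a minimizer needs before it can be selected. Because
`engine = "both"` was used, every record was computed by the forward and the
backward engine and compared field by field before being returned.

The DP arrays themselves are just as accessible:

```r
s  <- anchor_set(anchors(c(115, 215, 315), c(115, 215, 315), 15))
st <- chain_forward(s)
st$S; st$P; st$V
#> [1] 15 30 45    # each anchor extends the previous by its span
#> [1]  0  1  2    # predecessor indices (0 = chain start)
#> [1] 15 30 45    # running chain maximum
```

A thin command-line front end is installed with the package
(`<library>/anchorchain/exec/anchormap`) with `map`, `chain`, `verify` and
`simulate` subcommands over the same functions.

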