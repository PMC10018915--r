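---
title: "Anchor chaining by forward transformation: model, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor chaining by forward transformation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorchain)
```

## The problem

Long-read mappers work in a seed-chain-align pipeline. Seeding finds short
exact matches (*anchors*) between a read and a reference via a minimizer hash
index; chaining selects collinear, ordered subsets of those anchors
(*chains*) by 1-D dynamic programming, so that base-level alignment only has
to fill the gaps inside a few candidate regions. For noisy nanopore reads the
chaining DP dominates the total mapping time, and its classic formulation is
strictly sequential: each anchor scans *backwards* over up to 5,000
predecessors and keeps the best-scoring one, so no two anchors can be scored
concurrently.

This package implements both formulations of that DP over one shared scoring
function:

* `chain_backward()` — the sequential predecessor-order DP, with the
  MAX_SKIP early-exit heuristic either active (finite `max_skip`) or
  disabled (`max_skip = Inf`, the exact DP);
* `chain_forward()` — the *forward-transformed* DP: anchors are processed in
  ascending order and each anchor **pushes** candidate scores to all
  successors inside its pre-computed successor range. All pushes from one
  source are independent, which is what makes the transform parallelizable
  on wide hardware; here it is valued as an algorithmic object whose output
  must be **bit-identical** to the exact sequential DP.

The equality of the two engines — same best score `S`, same predecessor `P`,
same chain-maximum `V` for every anchor, as integers — is the package's
central correctness property and the main thing its test suite checks.

## The chaining model

An anchor is a 3-tuple: reference end coordinate `x`, query end coordinate
`y`, span `w` (we store *end* positions, 0-based; the upstream convention
that makes the gap algebra below exact). For an earlier anchor `i` and a
later anchor `j`, with

* query gap `dq = y_j - y_i`,
* reference gap `dr = x_j - x_i`,
* gap difference `dd = |dq - dr|`,

the pair is unchainable (`NO_CHAIN`, an out-of-band `NA`, so that legitimate
negative scores stay representable) when `dr <= 0`, `dq <= 0`,
`dq > max_dist_y`, `dr > max_dist_x`, or `dd > bandwidth`. Otherwise the pair
contributes

```
score(i, j) = min(dq, dr, w_j) - trunc(dd * 0.01 * avg_span) - floor(log2(dd)) %/% 2
```

with `avg_span` the mean anchor span of the whole set (computed once before
the DP) and the log term zero at `dd = 0`. The first penalty term is the gap
cost (linear in the diagonal drift), the second the concave overlap/log
term; the match term is capped by the successor's span. All arithmetic is
integer: the linear term is truncated exactly as written, and the integer
log2 is a leading-zero count, so independent implementations can (and in the
tests do) reproduce the values bit for bit.

The DP recurrence is `S[j] = max(w_j, max_i S[i] + score(i, j))` with `P[j]`
the maximizing predecessor, and `V[j] = max(S[j], V[P[j]])`, the maximum
score seen between the start of `j`'s chain and `j` itself.

### Tie-breaks: the one place the transform is delicate

The sequential engine scans predecessors from nearest to farthest and
updates on *strict* improvement, so the **nearest** predecessor wins score
ties. That behaviour is normative here. The forward engine reproduces it
with the update rule

```
update j when  s > S[j]   or  (s == S[j] and S[j] != w_j)
```

i.e. `>=` everywhere, *except* that a candidate tying an anchor's own span
never displaces a not-yet-chained anchor. Because sources arrive in
ascending order, the last writer on a genuine tie is automatically the
nearest predecessor. A plausible alternative — requiring strict improvement
from the immediately preceding anchor only — breaks equivalence exactly when
the set of best predecessors contains `j - 1` plus a farther anchor at equal
score; the test suite contains a three-anchor fixture (two duplicate
predecessors and one successor) that distinguishes the two rules, and the
differential tests over tie-rich coarse-grid anchor sets would catch any
regression.

A second subtlety is *when* `V[i]` may be finalized in the forward order:
every update into anchor `i` comes from a source with a smaller index, so at
the moment the ascending loop reaches `i`, `S[i]` and `P[i]` are final and
`V[i]` can be computed before `i` pushes anything.

### Successor ranges and the condensed workload

Because anchors are sorted by reference position, the successors of anchor
`i` eligible for chaining form a prefix run: all `j > i` with
`x_j - x_i <= max_dist_x`, capped at `max_range` (5,000) successors.
`successor_ranges()` finds the run boundary by probing the offsets
`{0, 16, 512, 1024, 2048, 3072, 4096, 5000}` in order, stopping at the first
probe past the threshold and decrementing back to the exact boundary; probes
past the last anchor count as out of threshold. The ladder reflects how
skewed real range distributions are — most anchors have no successor at all
and the vast majority have very few — so the expected number of iterations
is tiny, while the answer provably equals a full linear scan (the heuristic
saves iterations, never changes the result; the tests compare it to an
independent linear-scan oracle on every set, including a 6,000-anchor ladder
that exercises the cap).

`condense()` lists the anchors whose range is non-empty. Running the forward
DP with sources restricted to that list is exactly equivalent to running it
over all anchors — an anchor with an empty range pushes nothing — and the
suite asserts this on every test set. On realistic noisy-read anchor sets a
large fraction of anchors have empty ranges, which is what makes the
condensation worthwhile for batched execution; `scripts/acceptance.R`
reports the measured fraction on simulated data.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `k` | 15 | seed k-mer size; anchors have span `w = k` |
| `w` | 10 | minimizer window (k-mers per window) |
| `max_dist_x`, `max_dist_y` | 5000 | maximum reference/query gap (bases) |
| `bandwidth` | 500 | maximum `|dq - dr|` of a chainable pair |
| `max_range` | 5000 | predecessor/successor cap per anchor |
| `probe_deltas` | 0..5000 ladder | successor-range probe offsets |
| `max_skip` | `Inf` | skip heuristic off: the DP is exact |
| `min_score` | 40 | minimum chain score kept by backtracking |
| `min_cnt` | 3 | minimum anchors per kept chain |
| `mask_level` | 0.5 | query-overlap fraction that makes a chain secondary |

These follow the ONT mapping convention of the upstream long-read mapper
family. `max_skip` defaults to `Inf` deliberately: the finite heuristic can
only *miss* improvements (the suite exhibits a fixture where `max_skip = 5`
provably loses a chain), and only the exact DP is forward-transformable
without accuracy loss.

## Seeding

`extract_minimizers()` is classic (w,k)-winnowing: 2-bit-packed k-mers,
strand-canonical (the lexicographic minimum of k-mer and reverse complement;
palindromic k-mers skipped, which cannot occur for odd `k`), hashed with a
fixed unseeded 64-bit invertible mix, leftmost-minimum tie-break per window,
consecutive windows reporting a position once. K-mers covering non-ACGT
characters are skipped. `build_index()` stores every occurrence in a
hash-keyed multimap; `collect_anchors()` turns read-vs-index hash matches
into anchors, mapping reverse-strand hits onto the reverse-complemented read
so chaining is strand-agnostic. Determinism is total: same input, same index,
same anchors.

## Downstream of the DP

`backtrack()` visits anchors in descending `(S, index)` order and follows
predecessor pointers until a used anchor or a chain start, so no anchor is
ever reused; a chain truncated at a used anchor keeps only its suffix score.
`identify_primary()` sorts chains by score and masks chains whose query
interval is mostly covered by a better primary (fraction `mask_level`).
Mapping quality uses the upstream mapper's empirical form,
`40 (1 - f2/f1) min(1, m/10) ln f1` clamped to [0, 60] — confidence rises
with score and anchor count and collapses when an equally good secondary
placement exists. The formula is isolated in `mapping_quality()` so it can
be swapped without touching chaining. `V` is not consumed by backtracking
(no downstream consumer is prescribed); it is validated in the tests as the
maximum of `S` along each backtrack path.

`map_reads()` glues the stages together (index, per-length read bins,
anchors, chaining, backtracking, primary identification, PAF). With
`engine = "both"` every read is chained by both engines and the PAF records
are compared field by field, aborting on the first difference — the
differential mode the acceptance checks use end to end.

## Synthetic data: what it does and does not emulate

All tests run without downloads, on three generators:

* `plant_chains()` plants collinear anchor runs (per-link gap difference
  uniform in ±`gap_jitter`) in uniform background noise. Defaults: 2 chains
  of 25 anchors, `gap_mean = 100`, `gap_jitter = 20`, noise 5× the planted
  anchors, read length 12,000, reference span `ref_length` 1 Mb. The jitter
  default models the diagonal drift indel errors cause between successive
  seeds — at a 100-base gap and ~5-10% indels, drifts of a couple dozen
  bases — and stays far below `bandwidth`, so planted links remain
  individually profitable (`penalty(dd = 20) = 5 < 15 = match`). The
  reference span matters more than it looks: spurious seed hits scatter over
  the whole indexed reference, so noise reference coordinates must be drawn
  at genome scale (here the same 1 Mb the end-to-end tests use; real
  references are larger still). Compressing them into a few read lengths
  makes uniform noise dense enough to chain across multi-kilobase query
  gaps, which no realistic spurious-anchor background does. Uniform noise
  yields many empty-successor-range anchors, qualitatively matching the
  sparsity that motivates condensation; it is a tunable, not a calibrated
  fit.
* `simulate_read()` applies i.i.d. substitutions and single-base indels to a
  reference window, optionally reverse-complemented. Real nanopore error is
  homopolymer-biased and bursty; none of that is modelled, so passing tests
  demonstrate the chaining engine's behaviour under idealized noise, not
  platform-accurate mapping rates.
* `sample_read_lengths()` draws from a clipped log-normal mixture whose
  defaults give a long-tailed profile with mean near 8.25 kb, the scale of a
  typical nanopore WGS run; it feeds the read-binning policy
  (`bin_reads()`: 1 kb bins to 10 kb, 5 kb bins to 50 kb, then wide 50-100
  and 100-150 kb bins — long reads vary too much for narrow bins to fill).

Every generator is a pure function of its arguments including `seed`, and
restores the caller's RNG state.

## Numerical and design choices

* **Penalty arithmetic order.** `trunc(dd * 0.01 * avg_span)` is evaluated
  in exactly that operand order in both the C++ engines and the pure-R test
  oracle, so IEEE double rounding is identical and integer equality is
  meaningful.
* **Brute-force oracle independence.** The test oracle recomputes
  `floor(log2(dd))` from `log2()` with an explicit power-of-two correction
  rather than a leading-zero count, and evaluates all pairs exhaustively —
  a different code path from both engines.
* **Degenerate inputs.** Empty anchor sets chain to empty states; a single
  anchor scores its own span with no predecessor; duplicate anchors are
  legal (zero reference gap makes them mutually unchainable); ties in
  `(x, y)` keep input order (stable sort), which pins down the
  nearest-predecessor tie-break.
* **Problem sizes in the suite.** The differential tests run 1,000 anchor
  sets of 1-2,000 anchors across five generator regimes; the brute-force
  cross-check runs 200 sets of up to 300 anchors; end-to-end self-mapping
  uses a 1 Mb reference and 500 simulated reads of 1-50 kb, error-free and
  at 5% substitutions + 5% indels. These sizes give the differential
  properties room to fail while keeping a laptop-scale run.
* **What is out of scope.** Base-level alignment (and therefore CIGAR/SAM),
  spliced or long-gap chaining variants, RMQ-based chaining, frequency-based
  seed filtering beyond a simple occurrence cutoff, and any modelling of the
  hardware-level concerns (occupancy, memory layout) that motivate the
  forward transform in accelerator settings.

## A worked example

```{r example}
p <- map_params()
ref <- c(chr1 = random_reference(50000, seed = 5))
reads <- c(r1 = substr(ref[[1]], 10001, 18000),
           r2 = revcomp(substr(ref[[1]], 30001, 34000)))
paf <- map_reads(ref, reads, p, engine = "both")  # both engines must agree
paf[paf$tp, c("qname", "strand", "tstart", "tend", "nmatch", "mapq")]
```

Both reads come back as primary chains at their true windows, on the correct
strands, at mapping quality 60 — and `engine = "both"` certifies that the
forward-transformed engine produced byte-identical records to the sequential
one while doing it.
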