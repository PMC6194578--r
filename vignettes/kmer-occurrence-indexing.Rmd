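---
title: "Indexing k-mer occurrence across sequencing experiments with a two-level Othello"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing k-mer occurrence across sequencing experiments with a two-level Othello}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A collection of RNA-seq experiments can be summarized as, for every k-mer
observed anywhere in the collection, an *occurrence map*: an `m`-bit vector
recording the k-mer's presence or absence in each of the `m` experiments.
Arbitrary sequence queries (transcripts, fusion junctions, novel isoform
candidates) then reduce to looking up the constituent k-mers and
aggregating their occurrence maps into per-experiment hit counts and hit
ratios. The engineering obstacle is scale: billions of k-mers across
thousands of experiments rule out hash tables that store keys, and rule
out storing maps uncompressed.

`kothello` addresses this with three ingredients:

1. **The Othello classifier** — a minimal-perfect-hashing structure that
   stores a many-to-one map from a fixed key set `S` to categories
   `{1..v}` in two `l`-bit arrays (`l = ceil(log2(v+1))`), queried as
   `A[h_a(s)] XOR B[h_b(s)]`. It stores no keys, so a query on a key
   outside `S` (an *alien* key) returns an arbitrary but deterministic
   value; the analytic machinery below quantifies exactly how often that
   produces a false positive.
2. **Hybrid occurrence-map codecs** — value list, run-length delta list
   with a prefix-free hexadecimal token stream, or plain bitmap, whichever
   is shortest for the map at hand.
3. **A two-level layout** — a root Othello sends each k-mer either
   directly to its single experiment (the dominant `t = 1` case) or to a
   bucket of k-mers with similar encoded-map lengths; each bucket's own
   Othello maps the k-mer to a stored-map slot.

## The Othello structure

Keys are 2-bit-packed k-mer integers at the hashing boundary. A seeded
64-bit mixing hash (splitmix64) is split into the two array indices; array
lengths are the powers of two `m_a = 2^ceil(log2 n)` and
`m_b = 2^ceil(log2 (4n/3))`, which keeps `2.67 n <= m_a + m_b < 4 n` and
total storage within `4 n ceil(log2(v+1))` bits. Construction models the
`n` keys as edges of a bipartite multigraph over the array cells. If
degree-1 peeling removes every edge the graph is acyclic, and assigning
values in reverse peel order satisfies `A XOR B = value` along every edge;
any cycle (including two keys hashing to the same cell pair) triggers a
reseed, with a default cap of 100 attempts before an explicit failure. At
these load factors the acyclic probability per attempt is a healthy
constant, so one or two attempts are typical. Cells never visited during
assignment stay `0` — deliberately, because the alien-rejection bound
below counts on the mass at zero.

For an alien key the returned value `x` has probability
`p_x = sum_t a_t b_(x XOR t)`, where `a_t`, `b_t` are the fractions of
cells of `A`, `B` holding value `t` (the XOR convolution of the two cell
histograms). The probability that an alien key is *recognized* — maps
into `C - V = {0, v+1, ..., 2^l - 1}` — is
`P_Alien = p_0 + sum_(x=v+1)^(2^l-1) p_x`, and is bounded below by
`exp(-1.5) ~ 0.223` as `n` grows, because untouched cells alone give
`a_0 b_0 -> exp(-n/m_a) exp(-n/m_b) >= exp(-1.5)`.

`alien_value_distribution()` computes the convolution exactly for
`l < 12` (cost `O(4^l)`); for wider arrays it computes `p_0 = sum a_x b_x`
exactly and spreads the remaining mass evenly,
`p_(x != 0) = (1 - p_0)/(2^l - 1)`. Both paths are exposed (`exact =`)
so they can be cross-validated.

**A caveat on the flat approximation.** The even spread is accurate when
the category set fills the value width — which is the normal situation in
a bucket, since `l` is the smallest width that fits `v`. On constructed
cases where `v` is far below `2^l - 1` the approximation degrades
(we measured ~45% relative error at `v = 2100`, `l = 12`, versus ~4% at
`v = 4095`), because categories in `V` receive systematically more alien
mass than never-assigned values. The exact path should be forced if such
a structure is ever built deliberately.

## Occurrence-map codecs

For a map of `m` experiments with `t` set bits:

* **Value list** (`t * ceil(log2 m) <= 64` and `m >= 2`): the `t`
  positions, 1-based ascending, each stored as `position - 1` in
  `ceil(log2 m)` bits. The 0-based field is what makes the documented
  "single 1-bit index at m = 2" case work.
* **Delta list**: alternating run lengths
  `<x1, y1, ..., xw, yw, x(w+1)>` (leading and trailing 0-runs may be
  empty), each integer emitted as a prefix-free token of 4/8/12/16/32
  bits — the leading-zero count identifies the class, and every token is
  a whole number of hexadecimal digits. Integers at or above `2^28`
  overflow the widest class and are rejected (with runs bounded by `m`,
  this allows `m` up to ~268 million experiments).
* **Bitmap**: the raw `m` bits, experiment 1 at the most significant bit
  of byte 1. This bit-order convention is frozen and matches the
  left-to-right map strings used throughout.

`choose_encoding()` computes all applicable lengths and keeps the
shortest, breaking ties in the order value list, delta list, bitmap. An
all-absent map is never stored at index level; the degenerate one-element
delta list `<m>` exists only transiently inside group files.

## Construction pipeline

1. **Group merge.** Experiments are merged in groups of ~50; each group
   file carries one record per k-mer with its group-local, delta-encoded
   map. Group files are retained (optionally) because insertion of new
   experiments only requires appending new groups and repeating the later
   steps — the rebuilt index answers every query identically to a
   from-scratch build on the union, which the test suite checks
   end-to-end.
2. **Bucket ranges.** Encoded lengths are known only after encoding, so
   bucket boundaries come from a seeded sample of bucketed k-mers
   (`min(10^7, max(0.1% of total, 10^4))`): `L_i`, the sampled count at
   length `i` scaled by the inverse sampling fraction, feeds a greedy
   scan that extends each bucket's length range `[n_t, n_(t+1))` until
   the estimated payload `sum i * L_i` would exceed the capacity
   (default 128 MB; our test fixtures use 64 KB so the full machinery,
   including multi-bucket layouts, is exercised at desk scale). Sampling
   is taken over the k-mers that will actually be bucketed — the
   single-occurrence optimization removes `t = 1` k-mers first.
3. **Single-occurrence optimization.** k-mers present in exactly one
   experiment are encoded directly in the root Othello as that
   experiment's ID; everything else is assigned to the bucket containing
   its encoded length. Identical encoded maps within a bucket share one
   stored slot (k-mers map to slot indices, and slot counts determine the
   bucket Othello's `v_b`); the per-slot deduplication is recorded in the
   metadata so the false-positive model uses the actual slot counts.
4. **Othello construction.** Per bucket, an Othello maps its k-mers to
   slots `1..v_b`; the root Othello maps every indexed k-mer to
   `E ∪ B = {1..|E|} ∪ {|E|+1..|E|+|B|}`. All hash seeds derive
   deterministically from the build seed, so rebuilding with the same
   inputs and seed is byte-identical.

On disk an index is a directory: `meta.xml` (experiments, parameters,
bucket table with per-slot encoding kind and bit length), `root.oth`,
`bucket_<b>.oth`, gzip-compressed `bucket_<b>.maps.gz`, and optionally
`groups/`. `load_index(preload = FALSE)` defers payload decompression to
first access per bucket; both modes answer identically.

## Query semantics and the false-positive model

A sequence query is decomposed into its `|seq| - k + 1` windows; windows
containing non-ACGT characters are invalid — excluded from the valid
total `w` and shown as `.` in hit maps. Canonicalization (lexicographic
minimum of k-mer and reverse complement) matches build time, which is why
odd `k` in 15..31 is enforced: odd k-mers cannot be their own reverse
complement. Per k-mer, the root value routes three ways: an experiment ID
(present only there), a bucket ID (continue into the bucket, decode the
slot's map), or anything else (absent everywhere). For k-mers present in
at least one experiment the retrieved map is always exact; only alien
k-mers can produce false positives.

The analytic model composes the root and bucket alien profiles:

* per bucket, `P_b(e) = sum_(x in V_b) p_x W_(x,e)` with `W_(x,e)` the
  bit for experiment `e` in stored slot `x`;
* per experiment, `P(e) = p_e^root + sum_b p_(|E|+b)^root * P_b(e)`;
* overall recognition,
  `P_Alien = P_Alien^root + sum_b p_(|E|+b)^root * P_Alien^b`.

The test suite validates these predictions against a million uniformly
random alien probes on a 100-experiment build, per experiment, at three
binomial standard deviations. Over `w` alien k-mers the false-positive
count per experiment is `Binomial(w, P(e))`; `sequence_error_tail()`
evaluates its upper tail by direct log-space summation (no normal
approximation), e.g. `P[X > 2]` at `w = 50`, `P(e) = 0.00084` is about
`1.1e-5` — multiple coinciding false hits are vanishingly unlikely even
when single-k-mer false positives are not.

## Noise-aware fusion calling

A fusion junction query is built from the last `k - 1` donor-exon bases
and the first `k - 1` acceptor-exon bases, so all `k - 1` constituent
k-mers span the breakpoint. Querying the junction yields per-sample hit
counts in `0..(k-1)`. Repetitive junction k-mers present in a large
fraction of samples create a background floor; assuming true fusions
occur in under 2% of samples, the floor is estimated as `delta`, the
nearest-rank 98th percentile of the hit counts (the percentile is a
parameter — it should track the expected prevalence). A sample is called
when `hits >= delta + mu` (the `>=` convention; a strict variant is
available since the boundary convention is not otherwise determined), with
`mu = 7` as the default working point. The fixed-ratio alternative
(`hits/w >= theta`) is provided for comparison; on cohorts with a heavy
repetitive background it calls the background samples that the
noise-aware rule excludes, which is the behaviour the spiked-cohort test
pins down.

## The synthetic generators

`simulate_experiments()` emulates the *shape* of real k-mer occurrence
histograms — a large mass at frequency 1 (experiment-private sequence), a
substantial mass at frequency `|E|` (ubiquitous housekeeping-like
sequence), and accessory sequence at intermediate prevalence — using
random transcript pools. Defaults (100 experiments; 2 private transcripts
per experiment; 55 core transcripts; 250 accessory transcripts with
Beta(0.6, 1.8) prevalence; transcript lengths 900–1100) give a union of
roughly 5×10^5 distinct 21-mers with ≥30% at `t = 1` and ≥10% at
`t = |E|`. Ground truth is computed brute-force from the emitted files
themselves, so every downstream oracle is independent of the index code
paths. What the generator does **not** emulate: sequencing errors, read
coverage structure, shared biological sequence between "unrelated"
transcripts, or realistic base composition. Passing tests therefore
demonstrate structural correctness (exact retrieval, calibrated
false-positive behaviour) rather than biological fidelity.

`spike_fusion_cohort()` generates the fusion-calling scenario with exact
truth: a junction, a configurable number of its k-mers injected into
~99% of samples (the repetitive background, default 10 of the 20
junction k-mers so that the `theta = 0.5` rule demonstrably misfires), a
sub-2% set of spiked samples carrying every junction k-mer, and private
filler k-mers per sample. Infeasible designs (spike margin below 1, or
spiked fraction at or above 2%) are refused.

## Numerical and design choices

| Parameter | Default | Why |
|---|---|---|
| `k` | 21 | standard transcriptomic k-mer size; odd to avoid palindromes |
| group size | 50 | bounds simultaneous file handles; last group may be short |
| bucket capacity | 128 MB (64 KB in tests) | payload per bucket; unit interpreted as bytes of encoded maps |
| Othello reseed cap | 100 | acyclicity is likely per attempt; 100 failures signals a pathological input |
| exact/approx switch | `l < 12` | `O(4^l)` convolution becomes infeasible beyond that |
| noise percentile | 98 | matches the sub-2% fusion prevalence assumption |
| `mu` | 7 | conservative default margin above noise |

Other decisions worth recording: the value-list field stores `pos - 1`
(0-based) so field widths follow `ceil(log2 m)` exactly; hexadecimal
streams are padded with zero nibbles to byte boundaries while
`bit_length` keeps the unpadded length used for bucket assignment;
equal-length codecs tie-break value list > delta list > bitmap; bucket
slots are ordinal indices with byte lengths recorded in the metadata
(rather than raw byte offsets); and empty estimated buckets are dropped
and renumbered before IDs enter the root Othello.

## Problem sizes used in validation

The shipped tests and the reproduction script run entirely on synthetic
data at desk scale, chosen so the full suite completes in a few minutes
on one CPU: classifier studies at `n = 10^5` keys with 10^6 alien probes;
a 100-experiment cohort of ~5×10^5 distinct 21-mers for exact-retrieval
and false-positive calibration; a 2000-sample spiked cohort for fusion
calling; and a 30-experiment cohort for build-versus-insert equivalence.

## Known limitations

* The flat alien-mass approximation is only trustworthy when `v` is near
  `2^l - 1` (see the caveat above); `kothello` switches to it purely on
  `l`, as specified, but exposes the exact path.
* Serialized files are this package's own format; no attempt is made to
  read index files produced by other Othello-based tools.
* The index answers presence/absence only — abundances from k-mer count
  files are deliberately discarded.
* Online querying means preloading into the current process; there is no
  client–server protocol.
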