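# kothello

Large collections of RNA-seq experiments are, for search purposes, a set
of *k-mer occurrence maps*: for every k-mer observed in the collection, an
m-bit vector recording its presence or absence in each of the m
experiments. `kothello` builds a compressed index of those maps and
answers arbitrary sequence queries — transcripts, gene-fusion junctions,
any candidate sequence — with per-experiment k-mer hit counts, hit ratios
and hit maps, in constant time per k-mer and without storing the k-mers
themselves. It is aimed at people who need containment-style search over
many sequencing experiments (which samples express this junction? how
prevalent is this transcript?) where re-aligning raw reads is not an
option.

## The structure

The key→value machinery is the **Othello**, a minimal-perfect-hashing
classifier. A map `T : S -> {1..v}` over a fixed key set `S` (|S| = n) is
stored in two arrays `A`, `B` of `l = ⌈log₂(v+1)⌉`-bit cells with lengths
`m_a = 2^⌈log₂ n⌉`, `m_b = 2^⌈log₂(4n/3)⌉`, and queried as

```
τ(s) = A[h_a(s)] XOR B[h_b(s)]
```

— two array reads and one XOR. Construction treats keys as edges of a
bipartite graph over the cells and assigns values along an acyclic
orientation (reseeding the hash pair on cycles), so `τ(s) = T(s)` for
every constructed key and total storage stays within `4n⌈log₂(v+1)⌉`
bits. A key outside `S` ("alien") gets a deterministic but unconstrained
value; its distribution is the XOR convolution `p_x = Σ_t a_t b_{x⊕t}` of
the two cell-value histograms, and the probability an alien key is
correctly recognized (maps outside `{1..v}`) is
`P_Alien = p_0 + Σ_{x>v} p_x > e^{-1.5} ≈ 0.223` for large n.

The index is two such levels. The root Othello sends each indexed k-mer
either directly to its experiment (k-mers present in exactly one
experiment — the bulk of real data) or to a bucket of k-mers whose
encoded occurrence maps have similar bit lengths. Each bucket's Othello
maps its k-mers to deduplicated stored-map slots. Maps are stored under
the shortest of three codecs — a value list of set-bit positions, a
run-length delta list serialized as prefix-free hexadecimal tokens, or a
raw bitmap — and the whole-index false-positive probability per
experiment composes analytically from the root and bucket alien
profiles. A noise-aware fusion caller sits on top: junction queries built
from `k−1` donor + `k−1` acceptor bases (so every k-mer spans the
breakpoint), background noise estimated as the 98th-percentile hit count
δ, and occurrences called at `hits ≥ δ + μ`.

## Worked example

```r
library(kothello)

# a labelled synthetic cohort: 12 experiments sharing a transcript pool
sim <- simulate_experiments(n_experiments = 12, out_dir = tempfile(),
                            seed = 1, n_private = 1, n_core = 3,
                            n_accessory = 12, len_range = c(150, 250))
idx <- build_index(sim$manifest, k = 21, cap_bytes = 4096, seed = 1)
idx
#> kothello_index: 12 experiments, 4858 indexed 21-mers, 1 bucket(s)

# query one accessory transcript: hits / hit ratios per experiment
q <- query_sequence(idx, sim$transcripts$accessory[2], name = "acc2")
df <- data.frame(experiment = names(q$hits), hits = unname(q$hits),
                 ratio = round(unname(q$ratio), 3))
df[df$hits > 0, ]
#>   experiment hits ratio
#> 2     exp002  158     1
#> 4     exp004  158     1
#> 7     exp007  158     1
#> 9     exp009  158     1
q$w
#> [1] 158
```

All 158 valid 21-mers of the query hit exactly the four experiments that
contain the transcript (hit ratio 1.0) and none of the others — for
k-mers present anywhere in the collection, retrieval is exact. The
analytic false-positive model covers the alien k-mers:

```r
pred <- index_false_positive(idx)       # per-experiment P(e)
index_alien_recognition(idx)            # P_Alien for this build
#> [1] 0.6141
```

CLI equivalents of every step (`build`, `insert`, `query`, `info`,
`fpreport`, `fusion`, `simulate`) live behind `oth_main()` and the
`inst/cli/kothello` launcher.

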