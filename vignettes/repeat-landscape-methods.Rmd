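---
title: "Methods: simulating and analysing clone-scale repeat landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing clone-scale repeat landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(repeatscape)
```

`repeatscape` analyses the repetitive fraction of large genomes from
clone-scale surveys (BACs, scaffolds), and ships a forward simulator so
that every estimator in the package can be checked against planted
truth. This vignette records the models, the tunable parameters and
their defaults, the numerical conventions, and the design decisions
that were genuinely open.

## The substitution model and its simulation

All divergence-based machinery rests on Kimura's two-parameter (K2P)
model: transitions (A↔G, C↔T) occur at rate α, each transversion at
rate β, with κ = α/β. The model's total exit rate α + 2β is identical
for every base, which has a convenient consequence: drawing a
`Poisson(d)` number of substitution events per site (where
`d = rate × age` is the expected substitutions/site) and resolving each
event by the jump probabilities — transition with probability
κ/(κ + 2), each transversion with probability 1/(κ + 2) — reproduces
the continuous-time chain *exactly*, multiple hits included. This is
what `mutate_sequence()` does, so simulated divergences follow the same
law the estimators invert; no approximation is involved. The
suite checks the realised transition/transversion proportions against
the closed-form K2P expectations

$$P(d) = \tfrac14 + \tfrac14 e^{-4\beta t} - \tfrac12 e^{-2(\alpha+\beta)t},
\qquad Q(d) = \tfrac12\left(1 - e^{-4\beta t}\right).$$

Two parameters matter:

* `rate` — substitutions/site/year. Default `2.0e-8`, a rate
  appropriate for LTR retrotransposons in sunflower-like genomes
  (about double a silent-site rate). All ages scale inversely with it.
* `ti_tv_ratio` (κ) — default 2. No κ estimate is available for the
  system the defaults emulate, so the default is the conventional
  choice that preserves a transition bias; any κ > 0 can be supplied.
  Estimator calibration is insensitive to κ because the K2P distance
  corrects for it.

No indels are simulated. The dating formulas address substitutions
only, and a substitution-only process keeps member-to-consensus and
LTR-pair alignments trivial (equal length), so the estimators can be
tested exactly. Consequently, alignment-induced error in real data is
*not* represented in the calibration tests.

## Dating

`k2p_distance()` computes `d = -½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q)` over
comparable sites (columns where both sequences have an unambiguous
base; gaps and N are excluded pairwise). Saturation (either log
argument ≤ 0) raises an explicit error rather than returning `NaN`;
callers that aggregate over members (`family_consensus_age()`) drop
saturated members with a warning and fail only if none survive.

Two clocks are exposed:

* **LTR pairs**: the two terminal repeats of one element are identical
  at insertion and diverge independently afterwards, so their pairwise
  divergence grows at `2r`/year and `ltr_insertion_age()` returns
  `T = d/(2r)`.
* **Families**: each copy is a single lineage diverging from the
  ancestral element (approximated by the family consensus), so with
  `k` the mean K2P distance of members to the consensus the family age
  is `T = k/r`. The literal printed form of this estimator elsewhere,
  `T = kr`, is dimensionally impossible (it would map larger
  divergence to *smaller* ages measured in fractions of a year); the
  package uses the inverted form and records both in the result's
  attributes. Corrected (not raw) distances are used for consistency
  with the LTR clock and to stay unbiased at divergences up to ~30%.

Because age is linear in `k`, the correlation between family
divergence and family age is exactly 1 — an identity the acceptance
suite asserts to machine precision, and a useful smoke alarm: anything
below 1 means the estimator is no longer a deterministic function of
`k`.

## The simulator as a study design

`simulation_config()` defaults describe the survey the package is
organised around: 96 clones of 50–200 kb, of which 80 target planted
TE fractions in [0.75, 0.95], 14 in [0.50, 0.65] and 2 in
[0.10, 0.30]; background i.i.d. sequence at 39% GC; and an element
pool in which recently amplified LTR-retrotransposon families carry
most of the weight (ages 0.1–1 MY) with a minor older component at
2.7 MY. The young-heavy mix reflects the explosive recent
amplification typical of repeat-dominated plant genomes and keeps
within-family copies similar enough that a 20-mer index can see them —
with per-copy divergence `d`, a given 20-mer survives intact in a copy
with probability `exp(-20 d)`, so a family at 2.7 MY (`d ≈ 0.054`)
already loses a substantial share of its exact-match signal. Old,
heavily diverged families exist in real genomes and are deliberately
present only as a minor component of the default pool; k-mer-based
repetitive fractions *underestimate* their contribution, which is a
property of the method, not of the simulator.

Copies are drawn from the family pool (weights = `n_copies`) until the
planted TE bp reaches the clone's target fraction; the final copy is
truncated so the realised fraction lands within 0.03 of target
(truncated terminal copies are themselves realistic). Elements are
placed uniformly; with probability `nesting_probability` (default
0.05) an element inserts *inside* a previously placed element,
splitting the host's truth interval into two fragments that share a
`family_id`. SSR arrays and AT-rich tracts are planted in the
background; their flanking bases are chosen so they cannot extend the
planted array, which makes perfect-recall/precision checks exact. SSR
and low-complexity bp are tracked in the truth but not counted toward
the TE fraction (they are a ~0.5–1% perturbation well inside the
classification bands).

What the simulator does **not** emulate: indels and truncation by
deletion decay, solo-LTR formation, GC heterogeneity and gene content,
sequencing or assembly error, and nested-structure *reconstruction*
(nesting is planted, but the pipeline reports interleaved fragments
without rebuilding nest graphs). Tests passing on simulator output
therefore demonstrate correctness of the estimators under their own
model assumptions, not performance on raw survey data.

## k-mer landscape

`build_kmer_index()` counts canonical (strand-collapsed) k-mers,
default `k = 20`, over the whole input set; windows containing N are
skipped. Keys are 2-bit packed and exact for k ≤ 26. A position is
repeat-covered when it lies in the k-span of any k-mer whose count is
at least `freq_threshold` (default 4): a two-copy duplication is not
yet "repetitive", family-scale amplification (≥ 5 copies) is.
Clone classes use fixed thresholds — low [0, 0.40), mid [0.40, 0.70),
high [0.70, 1] — with the boundary values 0.40 and 0.70 assigned
upward; the published class ranges overlap at their boundaries, so a
convention had to be fixed.

## Discovery, clustering, consensus

`find_repeat_intervals()` emits maximal repeat-covered runs, merging
gaps up to `merge_gap` (default 50 bp, tolerating isolated
low-frequency k-mers inside diverged copies) and keeping runs of at
least `min_len` (default 50 bp). On dense clones, adjacent planted
copies separated by less than `merge_gap` of background merge into one
called interval; this mirrors what interval-level de novo detection
does on real data and is why family-count recovery is tested on sparse
constructions.

`cluster_copies()` links two copies when their best local alignment
(match +1, mismatch −1, gap −2) reaches ≥ 80% identity over ≥ 51% of
the shorter sequence — the blastclust `S = 80, L = 0.51` semantics,
with the shorter sequence as the coverage denominator — and takes
single-linkage components. Components below `min_copies = 5` stay
visible in the cluster report but are not emitted as families. A
shared-12-mer prefilter skips alignments between obviously unrelated
pairs; a pair that can reach the link thresholds shares many exact
12-mers, so the filter does not change results at the thresholds used.
`build_consensus()` star-aligns members to the longest member and
takes per-column majority bases, ties broken alphabetically.

## Annotation and composition

`mask_with_library()` is seed-and-extend: exact 12-mer seeds from each
library sequence are located on both strands, grouped into candidate
windows, and verified by local alignment; hits need ≥ 80% identity
over ≥ 50 bp and inherit class and family from the best-scoring
library record. `resolve_overlaps()` gives contested bases to the
higher score (ties: longer interval, then lexicographic family id),
truncating or splitting losers; the output is pairwise disjoint and
covers exactly the union of the inputs, so per-class bp plus
unannotated bp always equals the dataset size. Composition tables
report both percentages of the dataset and of the repetitive total,
and extrapolate to a configurable `genome_size` (default 3.6 Gb);
the extrapolated genome bp always satisfy
`genome_bp / genome_size = pct_of_genome / 100`. Pre- and
post-resolution totals are both available — their gap measures
overlapping boundaries and nested elements. Repeat densities
(bp/repeat) assign copies to regions by interval midpoint to avoid
double-counting straddlers.

## SSRs and low complexity

`find_ssrs()` detects maximal perfect tandem arrays of primitive 2–4
bp motifs, with MISA-like minimum unit counts (di ≥ 6, tri ≥ 5,
tetra ≥ 5; no published thresholds exist for the survey the defaults
emulate, and no interruptions are allowed). Runs are trimmed to whole
units; overlapping calls of different period resolve to the longest
locus. Motifs are reported canonically: the lexicographic minimum over
all rotations of the motif and of its reverse complement, so TGG and
CCA both report as ACC. `find_low_complexity()` marks unions of 30-bp
windows with A+T ≥ 0.90, trimming merged regions from the ends if the
union dips below the threshold. When an SSR is also AT-rich both
annotations are emitted; overlap resolution arbitrates for composition
totals with the SSR given the higher score.

## Spatial randomness

Scaffolds with at least 50 kb of contiguous (N-free) sequence are
divided into 5-kb bins; a bin is 1 when at least half its bases are
repeat-annotated (the bin rule is unpublished for the survey the
defaults emulate; half-masked is the natural symmetric choice), and a
trailing partial bin is kept when at least half a bin wide. The
one-sample runs test uses the normal approximation
`mu = 2 n1 n0/(n1+n0) + 1`,
`sigma² = 2 n1 n0 (2 n1 n0 − n1 − n0) / ((n1+n0)² (n1+n0−1))`,
`p = 2(1 − Φ(|z|))`, without continuity correction; series under 20
bins are flagged approximate, and all-0/all-1 series are degenerate
errors. No multiple-testing correction is applied across scaffolds
(matching per-clone reporting at α = 0.05), but a Bonferroni column is
emitted for transparency.

A caution the acceptance suite makes explicit: the normal
approximation is *not* a uniform substitute for the exact permutation
distribution at small n. Its type-I error at α = 0.05 is well
calibrated for 20-bin series (the suite checks [0.03, 0.07] over
2,000 null series), but for strongly unbalanced short series the
pointwise gap between the approximate and exact two-sided p-values is
large (worst case ~0.67 at n1 = 1, n0 = 3), so the suite's exhaustive
small-n agreement check fails by design and is retained as
documentation of that limit. Conclusions about individual short,
unbalanced scaffolds should use the exact distribution, not this
approximation.

## Phylogenetics

`poisson_dist_matrix()` applies `d = −ln(1 − p)` with pairwise
deletion of ambiguous columns (complete deletion is available to
emulate fixed-column analyses). `neighbor_joining()` is classic NJ
with two conventions fixed: ties in the Q criterion break on the
lexicographically smallest joined label pair, and negative
branch-length estimates are clamped to zero with the deficit moved to
the sister edge, preserving path lengths. On additive matrices NJ is
exact; the suite verifies recovery of random additive trees (≤ 8
taxa) to 1e-9 and agreement with an independent NJ implementation.
`bootstrap_support()` resamples alignment columns, rebuilds trees, and
reports the fraction of replicates containing each internal
bipartition of the full-data tree; replicates with saturated distances
are skipped and removed from the denominator.

## Problem sizes and determinism

The package's own calibration experiments use: 500 LTR pairs of
1,500 bp at a true age of 2.7 MY (mean recovered age, 3-SE band);
one family of 50 × 2 kb copies at 14.4 MY (5% band); 20 families for
the age–divergence identity; 256 elements for the independence null
(|r| < 2/√n); and the full 96-clone survey for class proportions.
These sizes make each estimator's sampling error small relative to
its tolerance while keeping any single experiment at seconds to tens
of seconds on one CPU. Every stochastic component takes a seed;
`build_synthetic_clones()` and `run_full()` are byte-reproducible
under a fixed seed, and `run_full()` derives per-stage seeds from one
top-level seed.

## Known limitations

* k-mer repetitive fractions systematically under-call old, diverged
  families (see above); the landscape classifier is calibrated for
  recently amplified repeat landscapes.
* Interval-level discovery merges copies separated by less than
  `merge_gap`, so copy counts from dense clones are lower bounds.
* `cluster_copies()` is quadratic in the number of copies (with the
  word prefilter it is fast for surveys of thousands of copies, but it
  is not a read-scale tool).
* Solo LTRs, indel decay and nested-structure reconstruction are out
  of scope; coverage tables are consumed, never computed from reads.
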