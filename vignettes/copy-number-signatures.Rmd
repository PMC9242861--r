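---
title: "Copy number signatures from allele-specific profiles: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy number signatures from allele-specific profiles: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnsig)
```

# The model

`cnsig` analyses allele-specific copy-number profiles: per-segment integer
copies of the major allele A and minor allele B (A >= B >= 0), as produced
by allele-specific callers such as ASCAT. The package's unit of analysis is
a 48-channel count vector per sample.

## The 48-channel encoding

Every segment is classified on three axes:

* **Heterozygosity**: `het` (A > 0, B > 0), `loh` (A > 0, B = 0), `homdel`
  (A = B = 0).
* **Total copy number** (TCN = A + B): 0, 1, 2, 3–4, 5–8, 9+. The states
  are mutually constrained with heterozygosity — `homdel` forces TCN 0,
  `het` requires TCN >= 2 — so only 3 + 5 + 4 = 12 (state, TCN) pairs are
  valid.
* **Segment size**: (0, 100 kb], (100 kb, 1 Mb], (1 Mb, 10 Mb],
  (10 Mb, 40 Mb], (40 Mb, ∞) for `het`/`loh`; for `homdel` the upper bins
  collapse to (1 Mb, ∞), since homozygous deletions larger than a few Mb
  are rare and usually artefactual.

This yields 3 + 25 + 20 = 48 channels. A cohort of S samples becomes a
non-negative S × 48 catalogue matrix **N**, rows summing to per-sample
segment counts. Two boundary conventions are ours to fix and are covered by
unit tests: size bins take **inclusive upper bounds** (a 100 kb segment is
"0–100 kb", making the ">40 Mb" and ">1 Mb" labels literal), and segment
length is `end − start + 1` under 1-based inclusive coordinates. BED-style
inputs (0-based half-open) are converted once at the I/O boundary.

Samples with more than 25 Mb of homozygously deleted genome are removed
before signature analysis (`filter_homdel_burden()`, strict `>`): such
profiles are dominated by calling artefacts rather than biology.

## Signature extraction

Signatures are extracted by non-negative matrix factorization of
**N**ᵀ ≈ **W** **H** with the generalized Kullback–Leibler objective —
the maximum-likelihood objective when channel counts are Poisson, which is
also why each NMF replicate runs on a **Poisson-resampled** catalogue
(every entry replaced by a Poisson draw at its observed value): replicates
then see data perturbed exactly at counting-noise scale. Fitting uses the
classical multiplicative updates; the objective is non-increasing per
iteration (asserted in tests) and iteration stops at a relative change
below `tol` (default 1e-8) or `max_iter` (default 10,000).

For each rank k, `n_replicates` fits (default 250; smaller values are fine
for exploration and are what the test suite uses) are pooled and their
signature columns partitioned into k clusters on cosine distance. We use
`cluster::pam` — a k-medoids algorithm whose build/swap phases are
deterministic, which removes a restart loop and a seed without changing the
clustering objective. Stability is the mean per-cluster silhouette width on
cosine distance (defined as 1 at k = 1); consensus signatures are
re-normalized cluster centroids, and consensus activities are refit by NNLS
against the consensus signatures.

**Rank selection** is an explicit, configurable heuristic, not a
reproduction of any published tool's internals: the selected k is the
largest rank with stability >= 0.8 whose reconstruction error improves on
k − 1 by more than 5% *of the largest searched error*. Normalizing the
elbow by the rank-1 baseline rather than the previous error keeps the
threshold meaningful when absolute errors become small: improvements near
the true rank are a large fraction of the baseline, overfitting gains are
not. If no rank qualifies, the most stable rank is returned flagged.

## Consolidation and pruning

Signatures from multiple extractions (e.g. pan-cohort and per-subtype) are
pooled and clustered by average-linkage hierarchical clustering on cosine
dissimilarity. The cut level maximizes
`min(within-cluster average cosine to centroid) − λ · max(between-centroid cosine)`
(λ = 1): members must resemble their consolidated signature while
consolidated signatures stay distinct.

Redundant signatures are then pruned: for each signature a synthetic
1,000-segment sample is drawn from its channel distribution, multinomially
resampled (default 100 resamples — the number of resamples is not a
sensitive choice and is configurable), and refit by NNLS against every
subset of at most 3 other signatures (exhaustive subset search, feasible
for K <= 25). If the **median** resample is reconstructed at cosine > 0.95,
the signature is a linear combination and is removed; removals happen one
at a time, re-evaluating after each. Median aggregation is our choice —
robust to the resampling noise while still requiring the typical resample
to be reconstructable. One guard is ours: a signature that is the *unique
carrier* of a channel (only it has > 0.05 mass there) is never pruned,
because cosine similarity can exceed 0.95 even when a channel that only
this signature explains is entirely missed.

## Attribution

A reference set is attributed to a sample by sparse penalized NNLS
(`assign_signatures()`), with the penalty values add = 0.1,
remove = 0.01, initial-remove = 0.05 acting on reconstruction-cosine
deltas. The loop order is fixed and documented: (i) NNLS over all
signatures; (ii) an initial removal pass; (iii) a second removal pass at
the smaller penalty; (iv) an addition pass re-admitting dropped signatures
only for a cosine gain above 0.1; final NNLS refit on the surviving set.
Within a removal pass, signatures are dropped greedily (cheapest first)
**while the cosine stays within the penalty of the cosine at the start of
the pass** — a cumulative budget. Per-step budgets would allow many small
drops to accumulate without bound.

A geometric property of cosine penalties is worth knowing when
interpreting attributions: removing an orthogonal component of normalized
weight w costs about 1 − √(1 − w²) ≈ w²/2 in cosine, so a 0.05 budget
permits dropping components up to roughly 0.25–0.30 of a sample's weight
regardless of signature shape. Penalized attribution is therefore
deliberately sparse: minor contributions are zeroed, and recovered weights
of retained signatures are accurate. Users needing dense attributions can
set the penalties to 0, which reduces `assign_signatures()` to plain NNLS.

Reconstruction significance (`reconstruction_q()`) uses a Monte-Carlo null
of our own construction (no published procedure exists to reproduce): the
sample's total count is redistributed uniformly over its occupied channels
and re-assigned; `p = (1 + #{null >= observed}) / (1 + n_null)`, BH-adjusted
across the cohort. It calibrates the observed cosine against what the
signature set achieves on support-matched noise; it is not expected to
reproduce any published percentage of well-reconstructed samples.

## Whole-genome doubling

Ploidy is the covered-length-weighted mean TCN; pLOH the LOH fraction of
covered length (homozygous deletions count in the denominator only, since
LOH is defined as A > 0, B = 0). A sample is called once genome-doubled
when ploidy > −3/2·pLOH + 3 (LOH-adjusted ploidy 3) and twice doubled when
ploidy > −5/2·pLOH + 5 (LOH-adjusted ploidy 5); "above" is strict, so
boundary samples round down.

Doubling acts on signatures as a linear transform (`double_signature()`):
within every (heterozygosity, size) stratum, each TCN class's mass moves to
the next class (TCN 1 empties; 9+ absorbs 5–8 plus itself; TCN-0 channels
are untouched). Stratum and total mass are preserved; the map is linear,
so raw counts and normalized signatures transform identically. Iterating
the map at most 4 times drives all non-homdel mass into the absorbing 9+
classes. `gd_pairs()` reports signature pairs whose doubled/original
cosine exceeds 0.85 — analogous patterns separated by one doubling.

## Mapping signatures onto the genome

Per-segment mapping uses the natural posterior under a multinomial-mixture
reading of the factorization: a segment in channel c gets
`p_i ∝ attribution_i × W[c, i]`, normalized; segments with all-zero
products are reported unmappable and excluded downstream (and counted in
QC). The exact published per-segment rule is not printed anywhere we can
consult, so this formalization is declared rather than inferred.

Window enrichment tiles the genome into half-open 1 Mb windows; a segment
overlaps a window at >= 1 bp. The null redistributes the same segments
(lengths preserved) uniformly over the genome — genome-wide rather than
per-chromosome, a granularity we expose but default to the less-assuming
option. `p = (1 + #{null >= obs}) / (1 + n_boot)` is exact Monte-Carlo;
multiplicity is handled by a Westfall–Young max-statistic step-down
computed from the *same* bootstrap draws, which respects the discreteness
of Monte-Carlo p-values in a way BH does not.

Region association pools segments across samples into a 2×2
(overlap × assignment) table tested by two-sided Fisher's exact test, BH
across signatures; odds ratios are reported raw and Haldane-corrected when
a cell is zero. The arm-level aneuploidy map restricts to samples fully
explained by a near-diploid/near-tetraploid signature pair (normalized
attributions summing to 1 within 1e-6) with mixed attribution
(product > 0.15), then reports per-arm fractions of samples whose
length-majority TCN exceeds or falls below the diploid baseline of 2.
Stratum enrichment tests (attribution > 0.05, strict) × stratum membership
with one-sided Fisher tests, BH-adjusted; the 0.05 presence threshold is
applied to normalized attributions.

# The simulator

`simulate_cohort()` generates cohorts from parameterized evolutionary
processes with exact ground truth: each sample starts as a diploid (1, 1)
autosomal genome (sex chromosomes are excluded by default — whether to
include X is configurable, Y is always questionable in tumour profiles)
and accumulates whole-chromosome, arm-level and focal events at Poisson
rates, 0–2 whole-genome doublings, and optional chromothripsis. Mechanics
are fully ours and deliberately simple:

* copy numbers floor at 0 (a loss on a lost haplotype is a no-op);
* focal lengths are log-uniform on 100 kb–10 Mb so every size bin is
  exercised without tuning;
* CIN events are split uniformly before/after doubling; chromothripsis is
  applied last;
* chromothripsis partitions a region at sorted uniform breakpoints and
  alternately deletes one haplotype copy, oscillating between exactly two
  copy states, with optional amplification of retained pieces.

Profiles are emitted by replaying the event log from the diploid genome,
so the log reproduces the profile exactly — the basis of the truth-replay
tests. Chromosome lengths and arm boundaries ship as fixed hg19/hg38
tables; arm boundaries are cytoband-derived approximations of centromere
positions, consumed only by the simulator and the arm-level map.

The simulator emulates integer allele-specific *profiles*, not data: there
is no segmentation noise, no purity/subclonality, no oversegmentation, no
sequencing artefacts, and no selection. Passing recovery tests therefore
demonstrate the correctness of the pipeline's machinery on clean input,
not robustness to the failure modes of real copy-number calling.

## Study cohorts used by the test suite

Test problem sizes are chosen to exercise every code path at desk scale:

* **Three-process recovery cohort**: 200 samples — 70 diploid, 70
  once-doubled, 60 focal-LOH CIN (60 expected focal losses each, ~140
  segments/profile, a realistic burden for a CIN genome). The CIN rate was
  fixed by a separation requirement — pairwise process-spectrum cosine
  below 0.5 — because planted-signature recovery is only well-posed for
  separated processes. Extraction over k = 1..5 with 15 replicates selects
  k = 3 and recovers each process spectrum.
* **Mixture cohort for attribution**: 500 samples mixed from 4
  archetype-shaped signatures with Dirichlet(1) weights and 50–500
  multinomial segments.
* Calibration suites use 150–200 Monte-Carlo draws; exhaustive oracles
  enumerate all 2×2 tables up to total 16 plus random tables with margins
  up to 30, and all NNLS supports for K <= 5.

# Numerical choices and degenerate inputs

* NNLS is solved by the Lawson–Hanson active-set method
  (`pracma::lsqnonneg`); removal ties break toward the lowest column index.
* NMF updates add 1e-12 inside logs/divisions; divergence terms with
  observed 0 contribute only their reconstruction mass.
* Empty profiles yield all-zero catalogue rows; ploidy/pLOH are undefined
  (error from the computing functions, `NA` from `profile_summary()`).
* Zero-count samples get an empty, flagged attribution.
* Unordered allele columns (minor > major) are swapped with a warning;
  alleles are exchangeable so all downstream classes are unaffected.
* Segments spanning a centromere are classified as called, never split.
* Chromosome names are normalized by a configurable "chr" policy (default:
  strip); X is kept and Y dropped by default, both configurable.

# Known limitations

* The extraction stack is compatible-in-spirit with the consensus-NMF
  family of signature extractors, not bit-compatible with any of them; the
  rank-selection rule in particular is our own declared heuristic.
* Penalized attribution's sparsity bound (the w²/2 geometry above) means
  per-sample mixture weights below ~0.25 are often reported as 0 at the
  default penalties.
* The aneuploidy map reports length-majority TCN against a fixed diploid
  baseline of 2; it is meaningful only for the near-diploid/tetraploid
  sample subset it restricts to.
* Monte-Carlo window enrichment assumes windows of comparable size;
  chromosome-terminal part-windows are slightly conservative.
* No subclonal (non-integer) copy numbers anywhere in the stack.
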