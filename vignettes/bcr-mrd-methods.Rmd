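---
title: "Methods: BCR repertoire networks, MRD mining and clone phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: BCR repertoire networks, MRD mining and clone phylogenetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bcrmrd)
```

## The problem

The heavy-chain V(D)J rearrangement of a B cell is a clone-specific
barcode. In B-cell acute lymphoblastic leukemia (B-ALL), the leukemic
clone's B-cell receptor (BCR) dominates the repertoire at diagnosis;
during and after therapy, the same sequence family can be mined from
deeply sequenced follow-up samples to quantify minimal residual disease
(MRD). `bcrmrd` implements this workflow end to end: clonality calling on
sequence networks, longitudinal clonotype mining, secondary-rearrangement
detection through D-J "stem" barcodes, clone phylogenetics around the
central BCR, and the statistics that decide whether diagnosis and relapse
repertoires share more structure than chance allows.

## Sequence networks and clonality

A repertoire is a collapsed multiset of unique sequences with read counts.
`build_network()` joins two unique sequences when they have equal length
and Hamming distance exactly 1 — substitutions only, never indels. A
cluster (connected component) is a clone proxy: the clone's ancestor plus
its cloud of point-mutation variants. Design points:

* **N policy.** An N mismatches every base, including another N. This can
  only split clusters, never merge them, so ambiguous base calls cannot
  fabricate clonal structure. The default read filter
  (`max_n_fraction = 0`) makes this moot for most inputs.
* **Clonality cutoff.** A sample is called clonal when the largest
  cluster holds at least 2.5% of reads (inclusive). The cutoff sits above
  the 95th percentile of largest-cluster fractions observed in healthy
  repertoires, which `healthy_percentile()` estimates by linear
  interpolation of order statistics (the default sample-quantile
  definition). Fractions are read fractions, not vertex fractions,
  consistent with vertex size being proportional to reads.
* **Scaling.** Edge finding is quadratic per length class with early
  termination after the second mismatch (C++); unrelated V(D)J
  rearrangements diverge within a few bases, so the scan is effectively
  linear in practice. Equivalence with brute-force all-pairs components is
  asserted in the test suite over random repertoires.

## MRD mining

`define_signatures()` freezes every cluster at or above the clonality
cutoff in an index sample (typically diagnosis) as a clonotype signature —
the full vertex set, not just the dominant sequence. `mine_sample()`
matches a follow-up sequence when its minimum equal-length Hamming
distance to any signature member is at most 8 (inclusive). The mismatch
budget absorbs both somatic hypermutation drift and sequencing error
while staying far inside the distance to unrelated rearrangements, which
differ at a large fraction of positions.

* Matching is substitution-only, consistent with the network edge rule;
  an optional Levenshtein mode applies the same cutoff to edit distance
  for indel-tolerant mining.
* When a patient carries several signatures, each sequence is assigned to
  the signature at the smallest distance (ties to the lower clone id), so
  per-clone read fractions never double-count.
* Detection is defined as at least one matched read; the matched count is
  always reported so users can impose their own limit of detection.
* `correlate_external()` reports the ordinary-least-squares R² between
  log10 mined fraction and log10 of an external MRD covariate (qPCR
  transcript ratio, % blasts) over samples where both are positive;
  zero/missing pairs are excluded and counted, and a constant series is
  flagged degenerate with R² = 0 rather than an undefined slope.

## Stem sequences and secondary rearrangements

V replacement rearranges a new (upstream) IgHV gene onto an existing D-J
join, changing the V while preserving the junction. The invariant part —
the *N-IgHD-N-IgHJ* "stem" — therefore barcodes the clone across V
replacements. `annotate_repertoire()` places V and J by local alignment
(match +1, mismatch −1, a gap of length *k* costs 4 + (*k* − 1); score
floors 20 for V and 10 for J; ties broken by longer alignment, then
alphabetical gene name). The stem starts 3 bases downstream of the last
V-aligned position — exclusive of the boundary base, dropping the
positions whose segment assignment is most uncertain — and runs to the
read end. Stems are grouped single-linkage at one substitution,
`v_usage_per_stem()` tallies the V genes attached to a stem group by
exact substring search, and `stem_background()` sets a per-stem
false-positive threshold at the 99th percentile of its frequency across
healthy repertoires. Only sequences with more than two reads inside
clusters of at least 2.5% contribute stems, which suppresses
error-derived stems.

## Clone phylogenetics

`collect_clone_members()` keeps mined sequences observed at least twice in
diagnosis or relapse (singletons are the most error-prone) and labels each
member `both`, `diagnosis-only` or `relapse-only`. `align_members()`
aligns members around the central BCR — the most frequent member, taken as
the clone's common ancestor — by center-star alignment merged under "once
a gap, always a gap"; when all members share one length (the common case
for substitution clouds) the alignment is the identity. A pre-aligned
FASTA can be substituted wherever a `clone_alignment` is accepted.

`build_parsimony_tree()` fits unrooted maximum parsimony under Fitch
(unordered, equal-cost) states over {A, C, G, T} with the alignment gap as
a fifth state. Up to 7 tips the search is exact — branch and bound over
every unrooted topology. Beyond that, deterministic stepwise addition
(tips in decreasing count order) is refined by nearest-neighbor
interchange to a local optimum; the test suite checks the heuristic
against exhaustive search on small instances. The reported score is the
exact Fitch length of the returned topology; branch lengths come from a
Fitch backtrace rooted at a tip (every internal node binary), which
guarantees they sum to the score. Bootstrap support resamples alignment
columns (100 replicates by default, seeded). Likelihood-based model
selection is deliberately out of scope: pure parsimony keeps branch
lengths interpretable as substitution counts for star-like clones.

## Overlap statistics

Under the null hypothesis that only the central BCR survives therapy, the
variants observed at diagnosis and relapse are independent draws from the
population of possible variants. For alignment length *l* and distance
shell *d*, that population has

\[
N(l, d) = \binom{l}{d}\,3^d
\]

members (`mutational_combinations()`, exact below 2^53; a log-scale
companion serves the tail computations at any magnitude).
`overlap_pvalue()` computes the exact hypergeometric upper tail
P(X ≥ k) in log space. `diag_relapse_overlap()` tests every shell d ≥ 1
and combines feasible, populated shells by Fisher's method; shells where
the observed member count exceeds N arise from indel variants that
violate the substitution-only model and are flagged infeasible rather
than tested.

Two guards against mistaking artifacts for shared biology:

* **Independent-clone baseline.** `shared_mutation_baseline()` measures
  how often V-gene mutation positions coincide between clones that cannot
  share descent (same V, different J; or same V, different individuals) in
  healthy repertoires, using clusters of more than six unique sequences as
  clones. The per-pair statistic is |A∩B| / mean(|A|, |B|), whose
  expectation under independent uniform mutation is m/L.
  `compare_shared_mutations()` then applies a one-sided Mann–Whitney test
  — exact by full enumeration of rank assignments for combined n ≤ 20
  (ties handled exactly), tie-corrected normal approximation otherwise.
* **Error-profile separation.** `triplet_profile()` classifies mutations
  into the standard 96 pyrimidine-centric trinucleotide contexts
  (purine-reference positions strand-collapsed; terminal positions
  excluded and counted). `compare_profiles()` runs a per-context Fisher
  exact test with Bonferroni correction over the 96 contexts, separating
  AID-driven somatic hypermutation (WRC/GYW-enriched) from flat
  PCR/sequencing error. `error_site_overlap()` applies the hypergeometric
  overlap test to error-site positions in control samples, where the true
  sequence is defined as the most frequent one.

## The synthetic repertoire generator

Every stage is tested against `sim_config()`-driven synthetic data with
full per-read ground truth. The generator's defaults emulate the regimes
the pipeline targets, and were fixed once:

* **Germline**: 8 V (150 nt), 4 D (21 nt), 3 J (30 nt) segments,
  rejection-sampled to pairwise divergence of at least 20% of length so
  annotation is unambiguous; V names encode locus order for the
  V-replacement directionality property (replacements move strictly
  upstream).
* **Healthy repertoires**: 3000 cells with independent V(D)J events
  (uniform segments, geometric N-additions of mean 4), log-normal read
  counts (sdlog 1), SHM at 0.2% per base. This yields largest-cluster
  fractions around 0.5–1.5%, emulating the polyclonal background against
  which the 2.5% cutoff is calibrated; the generator verifies the cutoff
  and resamples on violation (counted).
* **Clones**: one ancestral rearrangement plus a star-like cloud
  (default 60 variants at truncated-geometric distances of 1–8
  substitutions, optional WRC/GYW hotspot weighting), ancestor always at
  plurality read count — matching the central-BCR structure of leukemic
  clusters.
* **Dilutions**: reads drawn binomially between clone and background at
  the configured ratio, then independent per-base substitution errors at
  0.1%. Substitution-only error is the default so the Hamming-based
  modules see their assumed noise model; an indel mode is not simulated.
* **Determinism**: the seed is mandatory; each stage derives its own
  sub-seed so stages are independently reproducible and byte-identical
  across runs.

What the simulator does *not* model — realistic gene-usage biases, clonal
birth–death dynamics, PCR amplification bias, platform-specific error
profiles — bounds what passing tests show: they validate the algorithms
against their stated models and planted ground truth, not performance on
any particular sequencing chemistry.

## Problem sizes and numerical choices

The shipped tests run networks up to ~500 unique sequences against
brute-force oracles (100 repertoires), dilution series from 10⁻¹ to 10⁻⁵
at depth 10⁵, exhaustive parsimony checks at up to 6 tips (50 instances),
100-seed diagnosis–relapse recovery at cloud size 60, and 20-seed profile
comparisons at read-weighted mutation totals of a few thousand — sizes
chosen to exercise every decision rule while keeping the suite fast.
Hypergeometric tails are exact pmf sums in log space (validated to 1e-12
against naive summation); quantiles use linear interpolation of order
statistics; all Monte-Carlo procedures take explicit seeds. Mutation
profiles weight mutations by read count by default in the worked
examples, matching how sequencing data is tallied; unweighted profiles
are available by omitting `counts`.

## Known limitations

* Reads are used in the given orientation; no reverse-complement rescue.
* The substitute read filter (length and N-fraction) is minimal by
  design; quality-score-aware filtering is out of scope.
* Stems are opaque barcodes: D genes are not named, and IMGT-numbered
  junction or CDR/FWR partitioning is not reproduced (a position-mask
  hook on profiles can substitute).
* Mined fractions are computed over all reads, not in-frame reads only.
* Parsimony beyond 7 tips is a local-optimum heuristic, as in any
  practical tree search.
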