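---
title: "Replicate-aware partitioning of phyllosphere communities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-aware partitioning of phyllosphere communities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyllopart)
```

## The problem

Leaf-surface (phyllosphere) bacterial communities sampled by amplicon
sequencing are noisy: read counts vary strongly between biological
replicates of the same plant genotype, and many OTUs appear on a single
replicate only. When the question is whether host genotype — here,
cuticular wax composition of *Arabidopsis thaliana* wild type and
*eceriferum* (*cer*) wax-mutant lines — shapes the community, that
replicate-to-replicate noise must be separated from reproducible
membership before any between-genotype statistic is computed.

`phyllopart` does this by working on presence/absence across biological
replicates. An OTU is

* **resident** if it is present in *all* replicates of at least one
  plant line, and **transient** otherwise (the complement — the two
  categories are disjoint and exhaustive by construction);
* **core** if it is resident and occupies at least
  `n_samples - core_slack` of all samples (default slack 1: present in
  all or all but one sample);
* **plant line-specific** if it is resident in some line and absent
  from *every* replicate of at least one other line;
* **uniquely present** (absent) in line L if it is resident (absent) in
  L and absent (resident) in all other lines.

All downstream beta-diversity statistics operate on the resident
community only, the subset whose membership is reproducible at the
replicate level.

## Category semantics and edge cases

Two definitional choices deserve comment, since the verbal definitions
admit more than one reading:

* *Transient as complement.* A literal reading of "absent from at
  least one replicate of a given line" overlaps the resident
  definition whenever an OTU is resident in one line and patchy in
  another. Only the complement reading makes transient + resident a
  partition whose counts add up, so that is what `partition_communities()`
  implements.
* *Core at sample occupancy.* Core membership is defined on sample
  occupancy (at least `n_samples - core_slack` of all samples), not on
  per-line residency. With every line replicated at least twice and
  `core_slack` no larger than (minimum replicates − 1), a core OTU can
  never be line-specific: missing a whole line would require missing at
  least two samples. The slack is exposed as a parameter so a stricter
  or looser line-level reading can be emulated; the property suite
  verifies the disjointness theorem over random designs.
* *Uniquely absent* requires residency in **all** other lines (the
  strict reading), not mere non-absence. This makes the unique-absence
  call symmetric with unique presence and robust to patchy lines.

Zero-count rows (which arise after rarefaction) are retained and
treated as absent everywhere, so table dimensions are stable across the
pipeline.

## Statistics

All permutation statistics share two conventions: p-values use the
never-zero estimator `p = (b + 1) / (n_perm + 1)`, and every function
takes an explicit `seed` that is consumed in a local RNG scope (the
caller's random stream is untouched). Exact enumeration replaces
sampling when the permutation space is small (`exact = TRUE`).

**Jaccard distances** between samples are computed on feature sets:
`d = 1 − |∩| / |∪|`, with `d = 0` for two empty samples.

**ANOSIM** ranks all `n(n−1)/2` distances (average ranks for ties) and
computes Clarke's `R = (r̄_between − r̄_within) / (M/2)` with
`M = n(n−1)/2`, so `R = 1` exactly when every between-group distance
exceeds every within-group distance. Pairwise comparisons restrict the
distance matrix to each pair of lines; with fewer than two members in a
group the pair is flagged untestable rather than silently skipped.

**Mantel** correlates the strictly lower triangles of two distance
matrices (Pearson) and permutes rows and columns of the second
simultaneously; the test is two-sided on |r|. The underlying similarity
formulation (Jaccard similarity, Euclidean "similarity") differs from
the distance formulation only in the sign of r — |r| and p are
invariant under decreasing affine maps — so the package standardises on
distances and documents the sign convention. When wax profiles are
measured per line rather than per sample, `expand_profile()` replicates
each line's profile to its samples (the only construction that yields
conformable matrices); the pipeline records this expansion in its
output metadata.

**NMDS** minimises Kruskal stress-1 with the primary approach to ties:
configuration distances are isotonically regressed (pool-adjacent-
violators, via `stats::isoreg`) on the dissimilarity order, and the
configuration is updated by a Guttman majorization step. A step-halving
safeguard guarantees the recorded stress trace is non-increasing, which
the tests assert. The first restart starts from classical metric
scaling (`cmdscale`), so exactly embeddable inputs converge to
numerically zero stress immediately; the remaining restarts are random,
and the best configuration over restarts is returned. Defaults:
`k = 2`, 8 restarts, 300 iterations, relative tolerance 1e-8.

**Clustering.** UPGMA and complete linkage are agglomerative with
deterministic tie-breaking (lexicographically smallest pair of cluster
member labels), so trees are invariant to input order. UPGMA merge
heights are half the inter-cluster distance, making the dendrogram
ultrametric with leaf-to-leaf cophenetic distances equal to the
averaged input distances — an ultrametric input is reconstructed
exactly. Complete-linkage heights are the merge distances themselves
(matching `stats::hclust`), since that tree is used for heatmap leaf
ordering, not for distance reconstruction. Trees serialize to Newick
with branch lengths via `ape`.

**Alpha diversity.** Shannon uses the natural logarithm and Simpson is
reported as 1 − D, matching the defaults of the vegan package these
estimators are delegated to; Pielou evenness is `H / ln S_obs`
(undefined at `S_obs ≤ 1`); Chao1 is the bias-corrected form
`S_obs + F1(F1−1) / (2(F2+1))`, finite when doubletons are absent; ACE
uses the classical rare/abundant cutoff of 10. When a sample has no
rare OTUs at all, ACE is undefined and is reported as `S_obs`.
Rarefaction subsamples without replacement (multivariate
hypergeometric), and the analytic rarefaction curve is the
hypergeometric expectation
`E[S(d)] = S_obs − Σ_i P(OTU i absent at depth d)`; a Monte-Carlo mode
exists and agrees within sampling error (asserted in the tests).

## The synthetic community generator

Because the raw survey data underlying this kind of analysis is rarely
available in re-runnable form, every stage is validated against
generated communities with planted ground truth. The generator
(`synthetic_spec()` + `generate_community()`) emulates:

* a 5-line × 3-replicate design with per-sample depths uniform on
  2,340–10,010 reads (the observed range of the motivating survey);
* per-line wax profiles over six compound classes (alkanes, fatty
  acids, aldehydes, alkyl esters, primary alkanols, additional
  components), with baselines set to the measured per-line class
  totals where published (e.g. alkanes 2.30 µg cm⁻² for the wild type
  versus 0.45–1.71 µg cm⁻² for the mutants) and interpolated within the
  measured ranges otherwise; replicate profiles add Gaussian noise
  (`wax_noise_sd`, default 0.15 µg cm⁻², the middle of the reported
  SDs);
* planted occupancy: 13 core OTUs present everywhere (minus independent
  dropouts at `p_dropout`), 35 line-specific OTUs present in all
  replicates of their resident lines, strictly absent from their absent
  lines and Bernoulli elsewhere, and 459 transient OTUs i.i.d.
  Bernoulli(`p_transient`) per sample — 507 OTUs in total, mirroring
  the motivating study's dataset size;
* a wax–community coupling `coupling` ∈ [0, 1]: each specific OTU picks
  an anchor line, and other lines join its resident set with
  probability `(1 − λ)·0.5 + λ·exp(−d_wax / s)` where `d_wax` is the
  wax-space distance to the anchor and `s` the median inter-line wax
  distance. At λ = 1 wax chemistry determines community sharing
  (inducing a true Mantel correlation); at λ = 0 the assignment is
  independent of chemistry. The default is λ = 1, the regime the
  analysis is designed to detect.

Occupancy and abundance are modelled separately — a presence mask times
a per-OTU lognormal abundance (σ = `abundance_shape`, default 1.5),
renormalised over the OTUs present in each sample and converted to
counts multinomially. Each present OTU receives one guaranteed read
before the multinomial remainder is distributed, so the planted mask is
exactly observable in the counts: "present" means detected. Without
this, rare OTUs would stochastically drop to zero reads and the
noiseless-recovery contract (classification equals planted truth when
`p_transient = p_dropout = 0`) could not hold.

What the generator does **not** emulate: sequencing-level noise
(chimeras, homopolymer errors), phylogenetic correlation among OTUs,
spatial or temporal autocorrelation of transient colonisation, and any
coupling between an OTU's category and its abundance. Passing the
recovery tests therefore demonstrates the correctness of the
partitioning and statistical machinery under the stated model, not the
biological validity of any particular survey.

### A calibration subtlety

With λ = 0 one might expect the sample-level Mantel test (community
Jaccard vs wax Euclidean) to be null-calibrated. It is not, and
deliberately so: both matrices retain line-block structure (replicate
wax profiles differ only by measurement noise, and replicate
communities share their line's specific OTUs), so samples are not
exchangeable and the Mantel permutation null is false even without
wax–community coupling. The genuine null calibration is at line level:
collapsing the community to per-line residency
(`line_residency_matrix()`) and comparing against the line wax means
gives uniform p under λ = 0, which the test suite verifies. This is
worth remembering when interpreting sample-level Mantel tests on
replicated designs in general.

## The pipeline

`run_pipeline()` chains the stages in the canonical order — filter
(taxonomy substrings, default `"chloroplast"`, then table-wide
singletons), rarefy to even depth (`"auto"` = smallest sample total),
classify, extract the resident community, then Jaccard distances,
ANOSIM by line with pairwise table, NMDS, UPGMA dendrogram,
complete-linkage heatmap ordering, Mantel against wax profiles, and
Venn counts — writing each artifact as TSV/Newick with the seed in its
header plus a JSON manifest. A single global seed is expanded into
per-stage seeds by a fixed affine derivation, so changing the
permutation count of one stage never perturbs another, and two runs
with the same configuration are byte-identical.

```{r pipeline-example, eval = FALSE}
g <- generate_community(synthetic_spec(seed = 1))
cfg <- pipeline_config(g$table, profile = g$profile,
                       out_dir = "phyllopart_run", seed = 1)
res <- run_pipeline(cfg)
res$partition
res$anosim
res$mantel
```

## Problem sizes and numerical choices

The test suite and the acceptance script run at the study's native
scale (507 OTUs × 15 samples), which completes in seconds per
replicate; calibration checks use 500–2,000 simulated datasets with
999 permutations each, sizes at which a binomial standard error of the
rejection rate is below 0.005. Distance computations use exact set
algebra on integer matrices; permutation p-value comparisons use a
1e-12 tolerance when comparing ranks or correlations for exceedance, to
make tie handling independent of floating-point noise. Degenerate
inputs are either errors (zero-variance Mantel, empty samples,
rarefaction beyond a sample's depth — each names the offending sample)
or documented conventions (Jaccard distance 0 between empty samples,
ACE = S_obs with no rare OTUs, evenness undefined at a single OTU).

## Known limitations

* Residency is binary in the replicates; with very unequal replicate
  numbers across lines, lines with more replicates are harder to be
  resident in. The classifier allows unequal designs but the burden is
  asymmetric — by definition, not by accident.
* The dendrogram of resident communities uses Jaccard distances;
  phylogeny-aware distances (UniFrac) would require an OTU tree, which
  is outside this package's scope and is clearly not emulated.
* Percent-of-reads summaries are computed on whichever count table is
  supplied (rarefied or not); the two are reported side by side by the
  pipeline rather than arbitrated.
* ANOSIM pairwise tests on 3 replicates per group have a minimum
  attainable p of 1/(number of distinct relabellings); significance
  thresholds below that are unreachable and should not be requested.
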