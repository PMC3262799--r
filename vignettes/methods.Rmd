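---
title: "Methods: cell-type-specific miRNA-mRNA repression inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific miRNA-mRNA repression inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircellnet)
```

## The model

The package targets one experimental design: several immune cell
subsets sorted from blood, each profiled in replicate donor pools on
both a miRNA and an mRNA platform, with expression on the log2 scale
after RMA-style normalisation (normalisation itself is upstream and out
of scope). Two biological premises drive the statistics:

* a transcript that helps define a cell type's identity is expressed
  in a small number of cell types (one to three) and far less in the
  rest, and three-cell-type patterns follow hematopoietic lineage
  (myeloid: neutrophils, eosinophils, monocytes, mDCs; lymphoid: T, B,
  NK cells, pDCs);
* a miRNA that represses a target by transcript degradation leaves an
  inverse expression footprint: across cell types, target abundance
  falls where the miRNA is high.

The method therefore chains four filters, each of which removes a
different class of false positive: sequence-based target prediction
(removed: genes with no seed site), negative expression correlation
(removed: predicted targets not actually degraded in these cells),
per-miRNA overlap enrichment (removed: miRNAs whose anti-correlated
genes hit predictions no more often than chance), and cross-cohort
replication (removed: cohort-specific artifacts).

## Specificity calling

For each transcript the analysis cell types (CD4/CD8 merged into "T")
are ranked by mean log2 expression, descending for up-calls and
ascending for down-calls, ties broken by cell-type name so results are
deterministic. A transcript must first pass a one-way ANOVA across all
cell types at BH-adjusted p < α (α = 0.05), adjusted across
transcripts. Then, for k = 1, 2, 3 in order, a call at k requires:

* **detection** — mean log2 ≥ 7 in each specific cell type (up), or in
  every *non*-specific cell type (down). The floor is inclusive
  (≥ 7.0) for determinism and configurable.
* **homogeneity** (k ≥ 2) — one-way ANOVA restricted to the candidate
  top/bottom group has unadjusted p ≥ α, i.e. the group is internally
  indistinguishable. Applied to both platforms for symmetry and
  switchable (`homogeneity_gate`).
* **boundary contrast** — Welch two-sample t between the samples of
  the k-th and (k+1)-th ranked cell types, BH-adjusted across all
  transcripts' boundary tests at that direction and k (the adjusted
  value is the reported p\*). A pooled-variance contrast is available
  (`boundary_test = "pooled"`); Welch is the default because replicate
  pools of different cell types have no reason to share a variance.
* **fold change** — 2^(difference of boundary means) at or above the
  platform gate: 4 for mRNA, disabled (1) for miRNA. The asymmetry is
  deliberate: miRNA signal ranges are compressed, and a fold gate
  would discard genuine miRNA signatures.

The smallest k that satisfies all gates wins, so each transcript
carries at most one up and one down call. Internally all gates are
computed from per-group sufficient statistics (means, variances,
counts), vectorised across transcripts; unit tests pin these statistics
to `stats::lm`/`stats::t.test` and the full rule cascade to a
brute-force oracle on small instances.

The BH family for boundary tests is per (direction, k) across
transcripts. Pooling miRNA and mRNA platforms into one family was
rejected because the two analyses use different gates and are run
separately; pooling k-levels was rejected because each k defines a
different null hypothesis.

## Correlation screening and the permutation cutoff

Profiles are z-scored (zero mean, unit variance, n−1 denominator;
constant profiles are flagged degenerate and excluded) and every
miRNA × mRNA pair is scored by Pearson correlation. The negative
cutoff is not fixed a priori: in each of 100 permutation rounds the
cell-type axis of the whole mRNA profile matrix is permuted once —
preserving gene–gene correlation, which keeps the null honest — and
FDR(c) = mean null count below c / observed count below c (denominator
floored at 1) is evaluated on a grid (−0.05 to −0.95, step 0.05). The
chosen cutoff is the most lenient c with FDR(c) ≤ 1%; if none
qualifies the result is explicitly undefined and the FDR curve is
returned for inspection.

Two profile bases are provided. `ztransform_profiles()` correlates
8-point per-cell-type mean profiles; `matched_sample_profiles()`
correlates sample-level profiles with the two platforms aligned by
(cell type, donor pool). The pipeline default is the matched-sample
basis, for a structural reason: with 8 profile points the permutation
null of a Pearson correlation is so broad (about 8% of null pairs fall
below −0.55) that a 1% FDR is unattainable at *any* cutoff — the
observed fraction below the cutoff cannot exceed 1, so FDR(c) can
never drop below the null tail probability. With ~40 matched samples
the null tail at −0.55 is ~10⁻⁴ and a 1% FDR is reachable; on the
default synthetic cohort the calibration lands on −0.55 to −0.60.
A stringent permutation FDR paired with a cutoff near −0.55 is
therefore only coherent on a sample-level basis, and that is what the
package does by default, keeping the cell-type basis as an option
(`correlation: basis: cell_type_means`).

## Overlap enrichment

Per miRNA m, let N(m) be the genes with r(m, ·) below the cutoff and
T(m) its predicted targets (predictions are pre-filtered to TargetScan
entries confirmed by ≥ 1 additional source) intersected with the
profiled gene universe. The null fixes |T(m)| and randomises target
identities uniformly over the universe — which makes the null overlap
exactly hypergeometric, a fact the test suite exploits as a
closed-form oracle. The empirical p uses add-one smoothing,
(1 + #{null ≥ observed}) / (1 + B), is BH-adjusted across miRNAs, and
each miRNA is assigned a 1% / 5% / none tier. Note the granularity
constraint: at B = 100 permutations the smallest possible p is ~0.0099,
and after BH across tens of miRNAs no adjusted p can reach 0.05; runs
that need tier decisions should use B = 1000, as the tests do. The raw
empirical p remains available for the alternative, threshold-style
reading of a permutation FDR.

## Replication, knockout validation, over-representation

Cross-cohort agreement uses the Jaccard coefficient |A∩B| / |A∪B| plus
a hypergeometric upper-tail p. The universe behind the p-value is a
required argument — it is a genuine analysis choice (profiled genes
after curation), not something the package can infer. Knockout
validation tests whether candidate targets are de-repressed when the
miRNA is removed: the statistic is the fraction of candidates with
linear fold change above the primary threshold (1.3; 1.5 reported
alongside), compared against same-size random draws from all predicted
targets with fold-change data, 1000 permutations, add-one smoothing.
Genes without fold-change data (e.g. no homolog in the knockout
species) are dropped with a warning. A generic hypergeometric
over-representation test against user-supplied gene sets replaces
ontology-database enrichment, which is out of scope.

## Network assembly

Edges are replicated (both-cohort) repression pairs whose miRNA
carries a specificity call. Before the degree filter, regulators of a
gene are collapsed when their seed sites coincide: two regulators are
seed-similar only when *every* site of *each* overlaps a site of the
other (0-based half-open intervals). Mutual complete overlap is
required because a regulator with any independent site contributes
independent evidence and must not be discarded; similarity groups are
connected components, represented by the lexically smallest miRNA
identifier, and every collapse is reported. Genes then need ≥ 2
distinct regulators (`min_degree`, applied after collapse, since
collapse removes redundant evidence first). Hubs are ranked by degree
with lexical tie-breaks; exports are SIF (`mirna represses gene`) and
GraphML with node annotations (kind, specific cell types, lineage).

## The synthetic cohort generator

`simulate_cohort()` emulates the study design, not microarray physics:

* 8 analysis cell types in two lineages, 5 replicate pools each
  (~40 samples per platform);
* log2 signal: unexpressed transcripts at mean 5 (below the floor of
  7), expressed transcripts with one base mean drawn from U[8, 12] and
  shared across cell types; Gaussian noise, sd 0.5, per sample.
  Gaussian log2 noise matches how RMA-scale residuals behave;
* planted specific transcripts shift the base by ±3 log2 (8-fold,
  comfortably past the 4-fold mRNA gate) in their k cell types; k = 3
  patterns are drawn within one lineage. Default planted counts follow
  the observed structure at desk scale: miRNA up (4, 5, 9) for
  k = 1..3 with (2, 0, 0) down; mRNA up (20, 10, 5), down (6, 3, 2)
  reproducing the strong up/down asymmetry;
* 6 coupled miRNAs receive 20 true targets each: a target's
  per-cell-type mean is its base minus `coupling_beta` (default 1)
  times the standardized miRNA profile. Coupled miRNAs are chosen for
  overlapping specificity patterns (broadest k first, then greedily by
  shared cell types) because multiply-targeted genes — 8 additional
  shared targets coupled to a pair of regulators sharing a cell
  type — require regulators whose profiles are compatible: a gene
  cannot anti-correlate strongly with two orthogonal profiles at once,
  which is geometry, not noise;
* every true link plus 20 expression-independent decoy predictions per
  planted miRNA enter the prediction table (sources
  targetscan + mirdb, disjoint synthetic seed intervals), so the
  correlation filter has genuine false predictions to remove;
* `simulate_second_cohort()` keeps the planted truth and redraws base
  means, noise and pools, by default on a 6-cell-type panel without
  the dendritic subsets, emulating an independent validation cohort.

The generator does **not** model probe-level artifacts, batch or scan
date effects, donor pooling chemistry, correlated gene modules beyond
the planted couplings, or heavy-tailed noise. Passing tests therefore
demonstrate that the statistics behave as designed under the assumed
model, not that real microarray data meet those assumptions — in
particular, scan-date confounding (present in real designs where cell
types are scanned on different days) would inflate apparent
specificity and is deliberately left to the analyst's QC.

## Numerical and design choices

* Ranking ties break lexically by cell-type name; fully constant
  transcripts carry an ANOVA p of 1, never a spurious call.
* FDR denominators are floored at 1; empirical p-values are add-one
  smoothed, so 0 never appears.
* The per-stage seeds of `run_pipeline()` derive from the global seed
  by fixed offsets, so any stage can be re-run in isolation and
  identical config + seed gives byte-identical outputs (verified by
  manifest md5 checksums).
* PCA outlier flagging (|PC1| or |PC2| score beyond 3 sd) is advisory:
  it reports, the analyst drops, matching how outliers are handled in
  practice.
* Problem sizes in the shipped tests and the acceptance script — 60
  miRNAs × 300 mRNAs at the default design, 50–100 simulation seeds
  per recovery estimate, 25 null seeds for FDR calibration — were
  chosen so the full suite documents the method's operating
  characteristics at desk scale; dataset-scale counts (tens of
  thousands of probesets) are not reproduced.

## Known limitations

* The boundary contrast is a two-group test between adjacent ranked
  cell types; a planned single-contrast ANOVA would differ slightly.
  Both readings fit the published description; the two-group Welch
  form is the minimal one and the pooled variant is exposed.
* With 100 permutations, enrichment tiers after BH are unreachable
  (granularity); use 1000 permutations when tier decisions matter.
* Negative correlation cannot distinguish direct repression from
  indirect co-regulation; replication and knockout validation mitigate
  but do not eliminate this.
* The probe curation keep-list (unique genomic mapping) is consumed as
  an input; its derivation is out of scope.
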