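---
title: "Methods: longitudinal miRNA response analysis with neomir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal miRNA response analysis with neomir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`neomir` re-implements, as a tested and reusable pipeline, a longitudinal
multi-omic analysis of miRNA expression change under neoadjuvant
antiangiogenic (bevacizumab) plus chemotherapy treatment in ER-positive
breast cancer. The design it targets: tumor biopsies at week 0 (before
treatment), week 12 (after anthracycline) and week 25 (surgery, after
taxane), two randomized arms (chemotherapy alone vs chemotherapy +
bevacizumab), miRNA microarrays on every biopsy, and matched mRNA and
reverse-phase protein data for an integrative stage. The clinical cohort
itself is not shipped; a synthetic cohort generator with planted ground
truth stands in for it, so that every statistical stage can be validated
end to end.

# The statistical pipeline

## Preprocessing

Each sample (array) is centered to the median of its observed log2 values
(`median_center`), removing array-level intensity shifts. Features observed
in fewer than 80% of samples are then removed (`presence_filter`); the
boundary is inclusive, i.e. exactly 80% presence is retained, matching a
rule that removes features expressed in *less than* 80% of samples.
"Expressed" is interpreted as "not missing after platform detection" — the
generator's missingness mask plays the role of the detection calls, since
no detection-call rule beyond missingness is available to the pipeline.
The filter is applied once, to all samples jointly, before any
stratified analysis (the alternative — re-filtering per time point — would
change the tested feature set between contrasts and is not used). Note that
centering and filtering do not commute: removing features changes each
sample's observed median. The pipeline always centers first, then filters,
and the filter then merely row-subsets the centered matrix.

## Clustering: PART (recursive gap thresholding)

Hierarchical clustering uses Pearson correlation distance `d = 1 - r`
(pairwise-complete observations) with average linkage (UPGMA), on either
axis. Cluster detection follows the recursive-thresholding scheme: at each
tree node the gap statistic selects a number of clusters `k`; if `k > 1`
the node is cut into `k` subtrees and the procedure recurses into every
part with at least `min_size` items; parts smaller than `min_size` become
outliers; a node with `k = 1` is a final cluster. Nodes smaller than
`2 * min_size` are not split further (no cut of such a node can produce
two admissible parts). At each recursion level the subtree is re-built
from the subset's own distance matrix — for UPGMA the recomputed subtree
can differ slightly from the global tree's restriction, and the recomputed
version is the one that reflects the subset's internal structure.

The gap statistic compares the log pooled within-cluster sum of squares
around cluster centroids (Tibshirani's dispersion `W`) between the observed
data and `n_ref` reference datasets drawn uniformly over each observed
dimension range, choosing the smallest `k` with
`Gap(k) >= Gap(k+1) - s(k+1)`. Two details matter:

* The **tree** is cut on Pearson/average linkage (the pipeline's clustering
  metric), but the **dispersion** is Euclidean. An early variant using mean
  within-cluster correlation distance as `W` was discarded: under a
  structureless null its gap curve is so flat that sampling noise flips
  roughly 16% of decisions toward spurious splits, while the
  sum-of-squares dispersion gave 0 spurious splits in 50 null datasets and
  full recovery of planted three-cluster structure.
* The uniform reference is the simplest variant (no PCA rotation). With
  *uniform* null data it is exactly calibrated; with heavy-tailed or
  strongly skewed null data it can oversplit. This is a known limitation
  of the plain gap reference and is inherited deliberately.

Hyperparameters (`k_max = 10`, `n_ref = 20`, `min_size = 5`, fixed seed)
are defaults in the range customary for this family of methods and are
exposed on every entry point. All reference draws are seeded; two runs
with the same seed are identical.

Cluster-clinical association uses Fisher's exact test on the cluster ×
category table (outliers and unknown-response samples excluded). The exact
network algorithm is used only for small tables — it is numerically
unstable beyond that — otherwise a seeded Monte-Carlo p-value with 1e5
draws is reported.

Cluster persistence across time points matches clusters by maximal Jaccard
overlap (greedy, larger clusters first, one-to-one within a time point)
and reports, per chain, the fraction of baseline members present in the
matched cluster at every week. The measure is label-invariant.

## Differential expression

All two-group comparisons are two-sample Wilcoxon rank-sum tests: exact
two-sided p-values when the pooled size is at most 20 without ties,
otherwise the normal approximation with midranks, tie correction and
continuity correction. Week contrasts (0 vs 25, 0 vs 12, 12 vs 25) are
**unpaired**: the biopsy sets at two weeks overlap only partially, and the
restricted complete-case analysis is the same operation on the
`complete_case_subset` patients. Benjamini–Hochberg adjustment is applied
within one contrast over exactly the features tested there (never pooled
across contrasts), and significance means BH FDR < 5%. Fold change is the
ratio of anti-logged group means of log2 values, `2^(mean_a - mean_b)`,
so a fold change of 0.28 for week 25 vs week 0 reads as a mean log2 drop
of about 1.84. Signature comparisons (the per-arm week-0-vs-25 signatures)
report the Venn partition and direction concordance within the overlap.

The nomenclature analysis parses miRBase names (`hsa-miR-4465` → 4465,
`miR-125b-2-3p` → 125; let-7 members carry no number) and reports, per
direction, the fraction of parseable names with family number above 3000 —
numbers are assigned in discovery order, so this fraction measures how
recently annotated a signature is.

## Correlation screens

miRNA–mRNA and miRNA–proliferation correlations are Pearson on
pairwise-complete samples with two-sided p-values from the t transform.
The multiplicity correction is Bonferroni over the *declared family* — all
pairs computed in one invocation — which is the conservative global
reading; records are kept when the adjusted p is at most 0.05 **and**
|r| ≥ 0.3, both boundaries inclusive. The proliferation score is the mean
of per-gene z-scored expression over a proliferation signature gene list;
a mitosis-count proxy can replace it for validation-style runs. Pooled
analyses across weeks treat repeated biopsies of one patient as
independent samples — a simplification the pooled design implies, flagged
here because it mildly overstates the effective sample size.

## The protein association model

For each (miRNA, protein, week), protein expression is regressed on an
intercept, polynomial terms of its in-cis mRNA up to `max_power` (default
2), and the miRNA linearly:

`protein ~ 1 + mRNA + mRNA^2 + ... + miRNA`

The mRNA polynomial absorbs a flexible transcript-to-protein relationship;
the miRNA coefficient is the **beta value**, the per-time-point
miRNA–protein association measure. Predictors are standardized before
fitting so beta is scale-free (invariant to affine rescaling of the raw
miRNA); the reported beta is therefore in protein units per miRNA standard
deviation. Significance is the two-sided t-test of beta = 0, BH-adjusted
within week across all pairs. The polynomial degree is the minimal model
satisfying the two constraints that define this stage (flexible mRNA
adjustment, a single scalar miRNA association); it is exposed as
`max_power` and is not claimed to reproduce any particular published
estimation scheme. Hubs are proteins ranked by the number of distinct
significantly associated miRNAs per week, with each protein's share of all
significant associations; beta stability pairs the betas of weeks 0 and 25
for pairs significant in at least one of the two.

For speed, the landscape fit solves the normal equations per pair via a
Cholesky factorization (numerically equivalent to the QR fit used by
`fit_protein_model`, verified to 1e-8 in tests); the full default-scale
landscape (627 miRNAs × 210 proteins × 3 weeks ≈ 395k fits) runs in well
under a minute.

## Target predictions and over-representation

Prediction tables are consumed as pre-exported TSVs (no live database
queries; database versions drift). TargetScan-style records are kept at
context++ score ≤ −0.35 (more negative = stronger); microT-CDS-style
records at miTG score ≥ 0.7. The source material's wording for the microT
rule is contradictory (it "eliminates" scores *above or equal to* 0.7 yet
calls them low-confidence, although miTG scores are
confidence-increasing); the standard reading — keep strong predictions,
score ≥ 0.7 — is the default, with `microt_invert` as the escape hatch for
exports that store an eliminated-confidence score. Cross-referencing joins
correlations, predictions and gene-level regulation and flags the
canonical repression pattern (predicted target, negative correlation,
opposite regulation); positively correlated predicted targets are reported
as such rather than suppressed, since they occur in practice and are
biologically informative. Over-representation is the one-sided
hypergeometric (Fisher) test against a gene-set collection, BH across
sets, with the mRNA matrix's genes as the default universe. This is a
generic stand-in for commercial pathway tools, not an emulation of any
proprietary knowledge base.

# The synthetic cohort

`generate_cohort` emulates the study design so that recovery, calibration
and determinism are all testable:

* **Design sizes:** 627 miRNAs; biopsies 97/65/79 at weeks 0/12/25;
  objective-response splits 68:22, 44:17, 47:27 per week, with the
  remaining samples coded `unknown` (mirroring patients whose baseline
  tumor volume could not be determined). Because the week-25 non-responder
  count (27) exceeds week-0's (22), patient pools are supersets across
  weeks: 68 OR + 27 non-OR + 7 unknown = 102 patients, with "first-k"
  nesting so later biopsy sets overlap earlier ones.
* **Noise model:** the marginal log2 intensity distribution is
  N(8, 1.5) — typical for log microarray intensities — decomposed into
  feature-level mean spread (sd 1.2), a per-patient random intercept
  (sd 0.5) that links a patient's biopsies longitudinally, and a
  per-sample residual (derived, 0.75). The decomposition matters: the
  *within-feature* noise (≈0.9) is what determines test power, and the
  planted response effect of 1.5 log2 units at the 68 vs 22 design then
  yields the high sensitivity the validation suite asserts. Tests remain
  two-sample despite the longitudinal link, as in the target design.
* **Planted structure:** miRNA clusters via shared per-cluster factors at
  a configurable within-cluster correlation; 20 response-associated
  miRNAs (±1.5 log2 in OR samples); arm-specific time effects — 139
  combination-arm and 251 chemotherapy-arm miRNAs with 126 shared (120 up,
  6 down; the 13 combination-only miRNAs 1 up, 12 down) — realized by week
  12 in the combination arm but only by week 25 in the chemotherapy arm,
  encoding the timing asymmetry the analysis is meant to detect;
  miRNA–mRNA partner pairs at Pearson 0.8; two miRNAs tracking a latent
  proliferation factor; and protein values generated *from* the
  polynomial-mRNA-plus-miRNA model with known betas, so refitting on
  noiseless data recovers them exactly.
* **Missingness** is completely at random at 5% on the miRNA layer only
  (the presence filter is its only consumer).
* **What it does not emulate:** probe chemistry, dye and batch effects,
  skewed or heavy-tailed intensity distributions, informative missingness,
  and correlation between clinical covariates beyond the planted
  response/proliferation links. Passing recovery tests on this cohort
  demonstrates that the statistics do what they claim under the design's
  sample sizes and effect scales — not that real arrays are this clean.

Synthetic target predictions (planted pairs strongly predicted by both
sources, plus weak and strong decoys) and gene sets (one set enriched in
the planted partner genes plus random sets) let the target/enrichment
stage run end to end.

# Numerical choices and degenerate inputs

* Exact Wilcoxon refuses ties and falls back to the corrected normal
  approximation; equal groups give p = 1.
* Zero-variance features are errors where they poison a whole stage
  (distance matrices, the proliferation signature) and flagged-and-excluded
  records where they are local (correlation screens, single landscape
  fits). Flagged records never count toward a Bonferroni family.
* A feature missing in an entire group yields an undefined fold change
  (flagged `NA`), not an abort.
* Strata with fewer than 3 samples are skipped with a warning.
* The landscape's residual sum of squares is clamped at zero to absorb
  roundoff in noiseless fits; `log W` is floored at 1e-12 in the gap
  statistic.
* Ties in persistence matching break toward the larger cluster; cluster
  labels are assigned in depth-first discovery order and are contiguous.

# Problem sizes used by the validation suite

The test suite exercises the full default design where the claim depends
on it (PART recovery at 60 × 90 with within-cluster correlation 0.8; power
at the 68 vs 22 week-0 split with 20 planted effects among 600 nulls over
10 seeds; the complete pipeline at 627 miRNAs × 241 biopsies, run twice to
prove byte-level determinism) and reduced cohorts (~80 miRNAs, ~104
biopsies) for unit-level checks where the property tested does not depend
on scale. Oracle-equivalence checks (BH step-up, Wilcoxon enumeration,
hypergeometric tails, brute-force UPGMA cophenetic distances) compare
against independent implementations written in the test code itself.

# Known limitations

* The gap reference is the plain uniform-over-ranges variant; on strongly
  non-uniform null data it can oversplit (PCA-rotated references would
  temper this but are out of scope).
* Pooled correlation analyses treat repeated biopsies as independent.
* The ORA stage is a generic hypergeometric screen; its results are only
  as meaningful as the supplied gene sets and universe.
* The bivariate protein model considers one miRNA at a time; co-regulation
  by several miRNAs shows up as several marginal associations, not a joint
  fit.
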