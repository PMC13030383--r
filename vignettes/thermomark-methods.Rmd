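---
title: "Methods: multi-omics thermotolerance screening with planted-truth validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-omics thermotolerance screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The analysis problem

Contrasting a heat-tolerant with a heat-sensitive plant genotype across
graded temperature treatments produces two linked matrices: metabolite
abundances (hundreds to thousands of features, six replicates per genotype
× temperature) and gene counts (three replicates). The scientific questions
this package operationalises are:

1. Which metabolites respond to temperature, and do the two genotypes
   respond through the *same* metabolites or different ones?
2. Which few metabolites are credible *biomarkers* of the tolerant
   genotype's response?
3. Which gene co-expression modules track those biomarkers, and which genes
   sit at the centre of those modules?

Each stage is a standard method; the package's value is wiring them into
one tested, seeded pipeline, and pairing them with a generator that plants
known answers so every stage's recovery behaviour is measurable.

# The synthetic-data generator

`sim_config()` fixes the study design: 2 genotypes × temperatures
25/30/35 °C × 6 metabolome / 3 transcriptome replicates. Temperature enters
as an ordinal dose (0, 1, 2): the simplest monotone encoding of a graded
stress.

**Metabolome.** Feature baselines are drawn on the log2 scale
(N(10, 1.5²)), per-observation noise is N(0, `noise_sd`²) with
`noise_sd = 0.5`, and abundances are `2^log2value` — log-normal, the usual
skewed intensity model for LC-MS data. A *shared marker* adds
`marker_effect` (default 2.0 log2 units) per dose step in both genotypes; a
*genotype-specific marker* only in its own genotype. `marker_effect` may be
a vector, planting graded effect sizes. The published scale of such
experiments (thousands of features) is emulated at 500 features: large
enough that noise dominates the feature set, small enough that the full
test suite runs in minutes.

**Transcriptome.** Each of 4 planted modules (sizes 60–120 among 1000
genes) has a per-sample latent factor; a module gene's log2 mean is
baseline + loading × factor + noise, with loadings uniform in [0.8, 1.2],
and counts are negative-binomial around `2^log2mean` with dispersion 0.1 —
conventional RNA-seq noise. Factors carry a `module_temp_weight = 0.5`
component of the (standardised) temperature dose, so module genes are
genuinely differentially expressed and the DEG stage has planted signal;
the remaining variance is sample-level noise, which keeps distinct modules
separable (expected inter-factor correlation 0.25).

**Trait metabolites.** One designated metabolite per module is rebuilt
jointly with the factor by a bivariate construction: for the replicates
that have a transcriptome partner, its log2 abundance is
μ + σ(r·f + √(1−r²)·z) with z orthogonalised against f, so the sample
correlation with the factor equals the target `module_trait_r` (default
0.7) *exactly*; surplus metabolome replicates get independent noise at the
same marginal scale. Exact control here means downstream module–trait
recovery error is attributable to module detection and eigengene
estimation, not to generator sampling noise.

**What the generator does not emulate** (by design): chromatographic and
batch artifacts, missing-at-random dropout, heteroscedastic per-feature
noise, correlated marker blocks in the metabolome, read-level sequencing
data. Passing recovery tests therefore demonstrates the pipeline's
behaviour under clean planted signal, not robustness to those artifacts.

# Differential screening

**PLS-DA and VIP.** `plsda()` is a NIPALS PLS2 fit on column-standardised
data against the centred one-hot response. VIP uses the standard
weighted-sum-of-squares formula over components; mean(VIP²) = 1 is asserted
as a postcondition after every fit (and checked against an independent
single-component oracle and against mixOmics in the tests). Zero-variance
features are excluded with a warning: they carry no discriminant
information and would break unit scaling.

**Validation.** Q² comes from stratified k-fold cross-validation (7 folds
by convention; folds assigned per class after a seeded shuffle). Permutation
p-values use the add-one estimator (b+1)/(B+1) over label-shuffled refits —
its floor 1/(B+1) avoids reporting zero, and both R²Y and cross-validated Q²
are permuted, since R²Y alone is optimistic at p ≫ n.

**DAM rule.** VIP > 1.0 and p < 0.05, both strict, mirroring the
conventional reporting rule; direction is the sign of the log2 fold change.
Fold changes use raw group means with a pseudo-count of half the smallest
positive matrix value, so zero means cannot produce infinities.

**DEG calling** delegates to edgeR (TMM size factors, tagwise dispersion,
exact test, BH), the established two-group count workflow, behind the
`select_degs()` interface with the conventional |log2FC| ≥ 1, FDR < 0.05
rule. A power note the tests encode explicitly: at n = 3 the standard error
of log2FC is roughly √(2(1/μ + φ)/n)/ln 2, so a two-fold change at
dispersion φ = 0.1 gives z ≈ 2.6 per gene — not enough for high recall
after FDR control with any calibrated caller. The planted-recovery test
therefore uses φ = 0.01, where the same effect is comfortably detectable;
at φ = 0.1 only null calibration is asserted.

**K-means patterns** z-score each gene (clustering by shape, not
magnitude) and use `stats::kmeans` with 10 random restarts keeping the
best inertia. Furthest-point seeding was considered and dropped: base R
does not expose it, and multiple restarts address the same local-minimum
risk.

# Forest-based consistency screening

One randomForest classifier of temperature per genotype — mixing genotypes
is an error, because the point is to compare two independently learned
response strategies — with 1000 trees and mtry = ⌊√p⌋.

**MDA scaling.** `mda_importance()` reports the mean decrease in accuracy
scaled by its standard error across trees (the conventional randomForest
display), with `scaled = FALSE` giving the raw accuracy drop. The choice is
deliberate: with redundant planted markers, trees spread their splits over
the redundant set, and the raw per-feature drop becomes a small, noisy
share of the total signal — two refits of the same data correlate only
weakly on marker-level raw MDA at 1000 trees. SE scaling cancels most of
that competition noise, which matters downstream because the consistency
score compares normalized importances *between* the two genotype models.
The raw scale remains the interpretable one (a lone perfect predictor loses
baseline − 1/3 accuracy when permuted, which a test checks).

**Consistency and categorization.** Importances are clipped at zero
(negative permutation importance is estimation noise), min-max normalized
within each model, and compared: consistency = 1 − |ñ_A − ñ_B|. "High
importance" is the model's 0.8 quantile of ñ (inclusive); `shared` requires
high-in-both plus consistency ≥ 0.8, favored classes are high in exactly
one model, everything else is uninformative — a guaranteed partition. Two
consequences the user should know: with many near-zero importances the 0.8
quantile sits low, so a noise feature has roughly a 1-in-5 chance of
counting as "high" in a given model, which (a) admits some jointly
unremarkable features into `shared` and (b) caps the favored classes'
per-marker accuracy near 80%. Both thresholds are exposed as arguments; the
defaults reproduce the qualitative behaviour of published
importance-consistency partitions, whose exact cutoffs are not recoverable.

**Rank concordance** is tie-corrected Spearman (average ranks) with a
two-sided t-approximation p. An identifiability point shapes how it is
tested: rank agreement is measurable only on features that carry signal.
With ten shared markers among five hundred noise features, the noise ranks
are exchangeable and rho is near zero *regardless* of how concordant the
markers are — which is exactly the regime real studies report. The
directional tests therefore contrast generator defaults (specific markers,
rho stays low) with a marker-dominated panel (100 features, 60 shared
markers with graded effects 0.5–3), where concordance must and does emerge.

# The biomarker cascade

Top-k (default 100) by the tolerant model's importance — the tolerant
cultivar's drivers are the screening target; which model the published
cascade used is ambiguous, so the model is an argument. The expression
filter keeps a candidate when it is more abundant on average in the
tolerant genotype across stressed samples, *or* significantly up-regulated
there at the extreme temperature (one-sided Welch test, directional claim →
directional test). The OR structure follows the published wording
("either highly expressed or significantly up-regulated"). A structural
limitation worth stating: for an exchangeable-noise candidate the
higher-mean clause is a fair coin, so about half the non-informative
candidates survive; the panel is a high-recall shortlist, not a pure set,
and its Jaccard overlap with planted markers is accordingly modest (the
acceptance script reports the measured value). Retention of planted
tolerant-relevant markers and rejection of sensitive-specific ones are the
sharp guarantees, and they are tested at ≥ 90%/≥ 80% levels.

# Co-expression modules

Unsigned convention throughout: adjacency |cor|^β with β = 9, the standard
unsigned TOM, average-linkage clustering of 1 − TOM.

**Detection is a fine cut followed by eigengene reunification.** A single
static cut is fragile at n = 18 samples: cut high (0.99) and chance
correlations between module factors, bridged by noise genes, fuse modules;
cut low (0.95) and loosely attached genes fragment away and small modules
fall below the size filter. `coexpression_modules()` therefore cuts at 0.97
keeping every branch of ≥ 3 genes as a proto-cluster, merges proto-clusters
whose eigengenes correlate above 0.75 (the same 0.25 cut height used for
conventional module merging — fragments of one module have eigengene
correlation near 1, distinct modules near their factor correlation), and
only then applies the minimum module size (50) and relabels by size.
A recursive gap-ratio branch splitter was prototyped and rejected: noise
genes restructure the dendrogram enough that the top split of a fused
branch rarely coincides with the planted boundary. Recovery at generator
defaults (4 modules, 1000 genes, 18 samples) is measured by the test suite
as adjusted Rand index against planted membership.

`detect_modules()` itself remains the plain static cut (default 0.97) with
the size filter — the transparent primitive — and `merge_modules()` iterates
eigengene-correlation merging to a fixed point; cut height 0 merges
nothing, by definition.

**Eigengenes** are the first left singular vector of the standardised
samples × genes module submatrix (unit norm), sign-oriented to correlate
positively with the module's mean standardised profile, so sign is
reproducible and flipping all genes leaves the eigengene invariant.

**Module–trait correlation** is Pearson with Student-t p on n − 2 degrees
of freedom, aligned by sample. Metabolome and transcriptome replicate
counts differ (6 vs 3); `align_traits()` matches same-replicate partners
when they exist and otherwise averages metabolome replicates within
genotype × temperature and broadcasts — both alignments are supported
because published practice is ambiguous here. Near-constant profiles
correlate as 0 with a warning rather than NaN.

**Soft threshold.** For each candidate power, the scale-free fit is the R²
of log10 frequency against log10 connectivity over 10 connectivity bins,
counted only when the slope is negative; the smallest power reaching 0.8 is
recommended, else the best fit. The study convention β = 9 is the default
everywhere; `pick_soft_threshold()` is for users bringing their own data.

# Hubs and enrichment

Hub genes are the top-50 nodes by interaction-edge degree within a module,
ties broken by weighted degree then gene id — fully deterministic. The edge
list is always a user (or synthetic) file; no online interaction database
is queried, keeping runs self-contained. Intramodular connectivity kIM is
the within-module adjacency row sum; grey genes get their value among grey
peers but are flagged as non-module.

Enrichment is the hypergeometric upper tail P[X ≥ k] with BH correction,
the de facto standard for over-representation; the universe defaults to all
annotated ids and should normally be set to all measured genes. Ids outside
the universe are excluded with a warning naming them.

# Pipeline, seeds and numerical conventions

`run_pipeline()` chains the stages and writes TSV tables, JSON for nested
results, and a manifest recording version, parameters, per-stage status and
output paths. One global seed fans out as seed+0 (generator), +1/+2
(forests), +3 (k-means), +4 (validation): stages are reproducible without
sharing random-number state, and two runs with the same config and seed
produce byte-identical outputs (the manifest differs only in paths). A
stage failure halts the run with the stage name after writing the manifest.

Conventions applied throughout: pseudo-count of half the smallest positive
value for log fold changes; strict inequalities in the DAM rule; average
ranks for Spearman ties but id-broken strict ranks in importance tables;
negative MDA clipped before normalization; correlations of near-constant
vectors defined as 0 with a warning; all counts validated as integral for
transcriptome matrices.

# Problem sizes and limitations

The test suite and acceptance script run the generator at its default scale
(500 metabolite features, 1000 genes, 36/18 samples) with 25-seed medians
for forest recovery, 5-seed medians for module recovery, and 100-seed
medians for module–trait recovery — sizes chosen so the planted effects are
at realistic signal-to-noise while the whole suite completes in minutes on
one CPU.

Known limitations: orthogonal-projection filtering (OPLS) is not
implemented — VIP comes from plain PLS-DA, and single-response VIP rankings
from the two approaches are close but not identical; the DEG caller is a
generic two-group edgeR workflow, not a reimplementation of any specific
vendor pipeline; the consistency score and category cutoffs are declared
substitutes for published quantities whose exact definitions are not
recoverable; and the expression filter's OR clause admits noise candidates
by construction, as discussed above.
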