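---
title: "Statistical methods behind cogmwas"
author: "cogmwas authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind cogmwas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmwas)
```

# Scope and data model

`cogmwas` implements the downstream statistics of a functional
metagenome-wide association study: everything after reads have been
assembled, genes predicted and annotated against a functional catalogue
(COG-style units nested in 26 one-letter categories and four broad
classes). The working objects are

* a `functional_profile` — a sample × function matrix of non-negative
  abundances with a per-sample group label and a declared unit (`counts` or
  `relative`, rows summing to 1);
* a `category_map` — function → category → class, where each category
  belongs to exactly one class and unmapped functions are an explicit,
  detectable condition rather than a silent default;
* a `clinical_table` — per-sample numeric indices (symptom scores,
  depression scales, fecal SCFA concentrations, cytokines) with missing
  values permitted and handled pairwise-complete.

Whether functional abundances represent gene counts, read coverage or
relative frequencies is left to the caller's declared unit: statistical
stages convert counts to relative abundances internally, and aggregation
conserves per-sample totals exactly, so all downstream inference is on the
compositional (relative) scale.

# Differential abundance

The workhorse is a permutational one-way ANOVA. For each function the
classical F statistic (between/within mean-square ratio) is computed on the
observed labels; its null distribution comes from randomly permuting the
group labels, with one shared shuffled label vector per randomization
applied to every function. Sharing the permutation across functions
preserves the cross-function dependence structure of the null draws and
makes the computation a single group-means matrix product per iteration, so
a thousand permutations over a thousand functions cost a few seconds.

p-values use the standard finite-sample correction p = (b+1)/(B+1), where b
counts null statistics at or above the observed one — no permutation
p-value can be zero, and in sampled mode the attainable floor is 1/(B+1).
This floor matters jointly with FDR control: with m simultaneous tests,
Benjamini–Hochberg can only push a floor-level p below q = 0.05 if
m/(B+1) · 0.05⁻¹ allows it, so B must grow with the testing burden (the
package warns below B = 99; network screening over thousands of pairs uses
B = 999 by default). When the number of distinct label assignments is at
most 10⁵, `mode = "exhaustive"` enumerates them all and the p-value is
exact. Constant (zero-variance) functions have an undefined F and are
reported with p = q = 1 and a flag rather than dropped silently.

Numerical tie handling: permuted F values are compared to the observed one
with a relative tolerance of 1e-8, because label assignments that are
mathematically equivalent (e.g. the mirror of a two-group split) reproduce
the observed F only up to floating-point rounding; without the tolerance an
exhaustive p-value of exactly 2/20 could come out as 1/20.

Pairwise contrasts between two groups use the Wilcoxon rank-sum test: exact
enumeration when the pooled sample is small (≤ 50 by default) and untied,
the tie-corrected normal approximation otherwise, and p = 1 by definition
when the pooled values are all identical (the statistic carries no
information, and the approximation's variance degenerates).

# Clustering

Samples are clustered in PCA space: profiles are column-centered, projected
onto principal components, and the components retained to reach 95%
explained variance feed a Euclidean dissimilarity into PAM. The number of
components fed to PAM is a genuinely open choice (raw-profile and
rank-correlation dissimilarities are available as options); 95% retention
was chosen so that the dissimilarity is effectively the full-profile
Euclidean distance with noise dimensions truncated.

PAM itself is the deterministic BUILD + SWAP algorithm: greedy seeding
(first medoid minimizes total dissimilarity, subsequent medoids maximize
the objective decrease), then best-improvement medoid/non-medoid exchanges
until no exchange lowers the objective, with ties broken by the
lexicographically smallest (medoid, candidate) pair. The result therefore
depends only on the dissimilarity matrix and k — there is no random
restart. Two properties follow and are tested: the objective never
increases across swaps, and the final solution is 1-swap-optimal. Global
optimality is *not* guaranteed — like any local search, BUILD+SWAP can stop
at a 1-swap-optimal configuration above the exhaustive-search optimum on
unstructured point clouds — and the test suite checks exact agreement with
brute-force medoid search only on structured instances (separated runs and
blobs) where the optimum is attained, alongside the 1-swap-optimality
invariant on random instances. k defaults to 3, with a silhouette-guided
scan over k = 2..8 available (`pam_scan_k`).

# Co-occurrence networks and complexity indices

Per study group, pairwise association between functions is Spearman's rank
correlation (average ranks on ties), computed on that group's samples only.
Permutation p-values re-order the samples of one side of every pair with a
single shared permutation per randomization; since Spearman r is Pearson r
on ranks, each null draw is one cross-product of a row-permuted and an
unpermuted standardized rank matrix. FDR is applied over the strict upper
triangle. An edge joins two functions when r ≥ 0.8 with q < 0.05 (positive)
or r ≤ −0.8 with q < 0.05 (negative); 0.8 and 0.05 are the package
defaults, chosen to make edges denote strong, multiplicity-controlled
associations.

Three summaries are derived. The *active index* of a node is its degree
divided by the number of possible partners, |V|−1. The *internal
complexity* of category c with n_c member nodes is the number of edges
inside c divided by n_c(n_c−1)/2 (zero when n_c < 2). The *interaction
complexity* of two categories is the number of edges between them divided
by n_c1 · n_c2. These are pair-normalized edge densities — bounded in
[0, 1], invariant to node relabeling, and small for large categories, which
is why interaction complexities in realistic networks sit at the 10⁻⁴
scale. They are this package's concrete definitions of category-level
connectivity; other definitions (weighted, motif-based) exist and are out
of scope. SparCC-style compositional correction of the correlations is
deliberately not applied: the edge rule operates on plain Spearman r, and
compositional artefacts (closure-induced negative correlation) are among
the reasons the generator plants *blocks* rather than asserting absolute
edge counts.

# Biomarker selection and discrimination

Biomarkers for a target group are the functions that pass, in order:

1. differential abundance across all groups (permutational ANOVA
   p < 0.01);
2. clinical relevance — Spearman correlation with at least one configured
   clinical index at p < 0.05 within the target group's samples, with
   Bonferroni correction over the indices tested per function (the default;
   `correction = "none"` reproduces the uncorrected variant, and both raw
   and corrected p-values are reported);
3. maximal group-mean relative abundance in the target group.

The conjunction is monotone in both thresholds (loosening never removes a
member), which is tested as a property.

Discrimination is one-vs-rest: the target group against all remaining
samples, stratified five-fold cross-validation, a random forest (500 trees,
√p candidate features per split — the library defaults, configurable) fit
on each training fold, and AUC computed from held-out class probabilities
by the Mann–Whitney rank statistic. Folds are re-randomized `n_repeats`
times (default 100) and the mean over all fold-repeats is reported,
together with a ROC band (min/max held-out TPR per FPR grid point across
repeats).

Selecting biomarkers on the full cohort and then cross-validating only the
classifier leaks selection information into the evaluation. The package
reproduces that two-stage procedure as the default *and* provides
`audit_discriminator()`, which re-runs the entire selection — permutational
ANOVA and clinical screen on the training samples only — inside every
training fold. A fold whose training selection is empty scores its test
samples with a constant (AUC 0.5 by the rank convention). On pure-noise
data the audited mean AUC is chance-level, which the test suite asserts;
the unaudited default on the same data can be optimistic, which is exactly
the point of shipping both.

# Cohort statistics

Contingency tables (e.g. sex by study group) use Pearson's chi-square
without continuity correction by default — the convention that reproduces
standard cohort-table statistics; Yates' correction is available as a flag
for 2×2 tables. Numeric indices use the classical equal-variance one-way
ANOVA and mean ± SEM summaries (SEM = sample SD with n−1 denominator over
√n, undefined for singleton groups). Feature × clinical-index screens
report Spearman r and two-sided p per pair, pairwise-complete over missing
values, exact below n = 8 on untied data and t-approximate otherwise, with
pairs under 4 complete observations flagged not-assessable. The post-hoc
pairwise procedure sometimes attached to cohort tables is intentionally not
implemented: no single convention is standard enough to guess.

# The synthetic-data generator

`simulation_config()` defines the generative model the whole test suite
relies on. Defaults mirror a four-group gut-microbiome cohort: groups HC,
IBS-D, DEP, COMO of sizes 15/22/15/13 (65 samples), 500 functional units,
and an expected sequencing depth of 10⁵ counts per sample — a scale at
which moderately abundant functions have stable relative abundances while
rare ones remain noisy, as in real shotgun data. Per sample:

1. a latent log-scale abundance vector is drawn: log-normal base
   abundances (sdlog 1.5, giving the heavy-tailed abundance distribution
   typical of functional profiles) plus Gaussian noise (sdlog 0.5); members
   of a planted block share a common factor so that their latent
   correlation equals the block strength;
2. group enrichments multiply the latent abundances of chosen functions by
   their fold factor;
3. the vector is closed to proportions and counts are drawn multinomially
   at the configured depth.

The recorded truth contains the per-group expected relative abundances:
because the latent noise variance is shared by all functions, the expected
relative abundance of function j in group g is the closure of
base_j · fold_gj, which makes every planted group-ratio recomputable
without re-simulation (tested at the 10% level against empirical means at
200 samples per group).

Clinical indices are linear in the *within-group* standardized rank of the
linked function's relative abundance plus independent Gaussian noise, so a
link of strength s targets Spearman ≈ s inside each study group. The
within-group choice is deliberate: a cohort-wide rank link attenuates
inside a group whenever the linked function is also group-enriched (the
group's samples occupy a compressed range of the cohort ranks), i.e.
exactly where per-group correlation screens measure it.

What the generator does *not* emulate: annotation error and multi-mapping,
sample-to-sample depth variation, zero inflation beyond multinomial
sampling, phylogenetic correlation between functions, and covariate
structure (age, sex, BMI). Passing tests therefore demonstrate that the
statistics behave correctly under a clean compositional model with planted
effects — not that any particular real cohort meets those assumptions.

# Problem sizes used in the test suite

The shipped checks run at study-design scale: 65-sample cohorts in the
default four-group layout; 1,000 all-null functions with 999 permutations
for type-I-error and FDR calibration (20 replicates); 60-function/60-sample
panels for network block recovery (20 replicates, 999 permutations);
25-seed paired AUC comparisons; and 100 replicates for planted-biomarker
recovery. These sizes give binomial confidence intervals tight enough for
the asserted bounds while keeping a full run in the low minutes on one CPU.

# Known limitations

* Permutation p-values are granular at 1/(B+1); FDR-controlled decisions
  near the floor need B sized to the number of simultaneous tests.
* Complexity indices are unweighted edge densities; they ignore edge signs
  and correlation magnitudes beyond thresholding.
* The random-forest stage uses library default hyperparameters; no tuning
  loop is provided, by design — the evaluation protocol, not the
  classifier, is the point.
* `enriched_in` breaks group-mean ties by the first group in label order;
  exact ties are essentially impossible on continuous abundances but the
  rule is documented for reproducibility.
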