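---
title: "Methods: depression-related subtyping and scoring of IBD transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: depression-related subtyping and scoring of IBD transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`ibddep` quantifies a depression-related axis in bulk IBD transcriptomes:
it derives a core-gene panel, splits patients into a low-inflammatory and
a pro-inflammatory molecular subtype by NMF consensus clustering, and
compresses the subtype contrast into a per-sample composite score (the
D.score) that can be stratified and associated with anti-TNF response. A
companion microbiome stage contrasts two treatment groups in 16S count
tables. This vignette records the model, its assumptions, the tunable
parameters, the numerical choices, and what the synthetic-data generators
do and do not emulate.

## The statistical chain

### Batch adjustment

`combat_adjust()` implements parametric empirical-Bayes location/scale
batch correction for log2 expression. Each gene is standardized under a
no-batch model (weighted grand mean, pooled variance); per-batch per-gene
locations get a normal prior and scales an inverse-gamma prior, both
estimated by method of moments across genes and refined by the standard
iterative conditional solve; the shrunken effects are removed and the data
back-transformed. `mean_only = TRUE` skips the scale step; `shrink =
FALSE` disables the EB pooling (direct standardization), which is also the
setting under which the per-gene grand mean is preserved *exactly* — under
EB shrinkage preservation is only approximate, because the prior pulls the
per-batch effects away from their zero-weighted-sum constraint. The test
suite cross-checks the adjusted matrices against `sva::ComBat` (max
absolute difference below 1e-3 on random multi-batch data).

Assumptions: batches share the biological signal (balanced design);
effects are additive on the log2 scale; every batch has at least two
samples. Zero-variance genes are passed through untouched and logged.

### Moderated differential expression

`moderated_ttest()` computes pooled-variance two-group t statistics with
gene variances shrunk toward a common prior: the log pooled variances are
fit to a scaled inverse chi-square by method of moments (digamma/trigamma
matching, with a Newton trigamma inverse), giving prior degrees of freedom
d0 and prior variance s0². The moderated statistic uses the posterior
variance (d0·s0² + d·s²)/(d0 + d) with d + d0 degrees of freedom, and
Benjamini–Hochberg adjustment across genes. d0 is capped at 1e6 to keep
the "infinite shrinkage" limit numerically stable; `d0 = 0` recovers the
ordinary pooled t exactly (tested against a first-principles oracle at
1e-10). `limma::eBayes` serves as an independent cross-check in the tests
(t correlation above 0.999; prior df within 20% when finite). The design
is strictly two-group with no covariates — the pipeline's two contrasts
(IBD vs healthy; subtype 2 vs subtype 1) both use it.

DEG selection is strict on both sides: adjusted p **<** 0.05 and |log2FC|
**>** 0.2, so a gene at exactly 0.2 is excluded; the adjusted-p direction
is taken as "less than". The same thresholds are reused for the
subtype-level signature pass, since no separate thresholds are specified
anywhere for that step; both are exposed in the configuration.

### NMF consensus subtyping

`nmf_factorize()` minimizes the generalized KL divergence D(A‖WH) with
Brunet multiplicative updates, implemented in C++ (RcppArmadillo).
Numerical choices:

* denominators are guarded with 1e-12; the divergence is computed as a
  constant term plus Σ WH − Σ A∘log(WH), vectorized, once per iteration;
* convergence = relative divergence change below `tol` (default 1e-6)
  over a 10-iteration window, or `max_iter` (default 2000);
* the scale ambiguity is resolved by normalizing columns of W to unit sum;
* initialization is uniform random, scaled to the data mean, from a
  per-run seed derived deterministically from the master seed;
* the divergence trace is recorded every iteration and asserted
  non-increasing in the tests.

`consensus_cluster()` assigns each sample to the argmax row of H (ties to
the lowest index, logged behaviour), averages binary connectivity matrices
over `n_runs` restarts (default 50), and derives final labels by
average-linkage hierarchical clustering of 1 − C — so labels reflect the
*consensus*, not any single run. Diagnostics:

* **cophenetic coefficient** — Pearson correlation between the
  dendrogram's cophenetic distances and the off-diagonal of 1 − C;
* **dispersion** — mean of 4(C_ij − ½)² over **off-diagonal** entries.
  The unit diagonal is excluded deliberately: with it included the
  maximally ambiguous all-½ matrix would score 1/n rather than the
  intended 0, while a binary consensus still scores exactly 1;
* **mean silhouette** width on distance 1 − C (via `cluster::silhouette`).

`select_rank()` returns the smallest k maximizing the cophenetic
coefficient, breaking exact ties lexicographically by dispersion, then
silhouette, then k. No stated rule exists for disagreement among the three
diagnostics, so this ordering is a package design choice; all per-k
diagnostics are returned so users can overrule it. When the best
cophenetic coefficient is below 0.9 the result carries a low-confidence
flag rather than an error — a pure-noise matrix still yields diagnostics.

Log-scale expression must be made non-negative first; `to_nonnegative()`
defaults to subtracting the global minimum (`offset`), with a
`posneg` mode (stacking positive and negative parts) available. The
choice is documented rather than prescribed, since nothing in the
upstream method fixes it.

`assign_subtypes()` orients the k = 2 clusters deterministically: the
cluster with the higher mean expression of a user-supplied inflammation
panel becomes `D.cluster2` (the pro-inflammatory, depression-like
subtype). This removes the arbitrary cluster-index ambiguity of any
clustering procedure.

### Single-sample enrichment, ORA, deconvolution

`ssgsea_scores()` is a weighted rank-ECDF single-sample scorer: per
sample, genes are ranked by expression; the score of a set is the summed
difference between the weighted in-set ECDF (weights = rank statistic to
the power `alpha`, default 0.25) and the unweighted out-of-set ECDF.
Because the weights are rank statistics, scores are invariant to strictly
monotone per-sample transforms at every `alpha`. This scorer is a fully
specified stand-in for kernel-based GSVA scoring, which is intentionally
out of scope; consequently downstream use is at the property level (group
contrasts of scores via `moderated_ttest()`), never score-value equality
with GSVA. Metabolic signature scoring reuses the same scorer with a
metabolic GMT — there is no separate code path.

`ora_enrichment()` is the one-sided upper-tail hypergeometric test with BH
adjustment across sets. Its calibration is tested with randomized
p-values (exactly uniform when the reported p is the true upper tail).

`deconvolve()` regresses each mixture sample on a cell-type signature
matrix, non-negative least squares by default (`pracma::lsqnonneg`), or
linear nu-SVR (`e1071`, nu ∈ {0.25, 0.5, 0.75}, best residual kept,
negative coefficients clipped) behind a flag. Features are restricted to
signature genes and each gene is *scaled* by its signature-row SD so genes
contribute comparably. Centering across cell types is deliberately
avoided: subtracting the per-gene mean forces the scaled signature columns
to sum to the zero vector, which loses one rank and makes the fractions
unidentifiable up to an additive shift. Scaling alone keeps the problem
full rank and makes noiseless mixtures exactly recoverable (tested to
1e-6). Fractions are renormalized to the simplex, matching the
"proportion of infiltration" reading; the per-sample RMSE and an optional
gene-permutation p-value are reported.

### The D.score

`compute_dscore()` standardizes each signature gene (mean 0, SD 1 across
samples) and runs PCA over samples; the per-sample score is PC1 + PC2.
Two open choices are resolved and recorded:

* **Space** — sample scores from the PCA of the standardized genes ×
  samples matrix (the convention of the scoring schemes this construction
  follows); gene-wise z-scoring first means the PCs reflect correlation
  structure, not raw variance.
* **Sign** — each PC's sign is flipped, if needed, so the mean score of
  `D.cluster2` exceeds that of `D.cluster1`; higher D.score therefore
  always reads "more inflamed". The applied signs are stored in the
  result for provenance.

Degenerate inputs error early: a constant matrix, or fewer than two
non-degenerate PCs. `stratify()` splits at the median by default (strict
">" to `high`), configurable to a fixed threshold; the median rule is a
package choice where no split rule is stated. `response_association()`
uses the Pearson chi-square without continuity correction (df = 1), with a
Haldane 0.5 correction for the odds ratio when a cell is zero; degenerate
tables are returned without a test rather than erroring.

`gene_cluster_consensus()` — the second, sample-space consensus grouping
on the signature genes — uses resampled k-means (80% sample draws,
k-means++ seeding feeding `stats::kmeans`, 10 restarts, co-assignment
frequencies conditioned on co-sampling) because no algorithm is named for
this second clustering and NMF is reserved for the subtype step. Cluster
names are oriented by the same inflammation-panel rule.

### Microbiome stage

Alpha diversity uses `vegan`: Shannon in natural-log units, bias-corrected
Chao1 (S_obs + F1(F1−1)/(2(F2+1))), and ACE with rare cutoff 10; when a
sample has no rare taxa both estimators reduce to the observed richness.
Bray–Curtis distances are computed on relative abundances and embedded by
classical scaling (`stats::cmdscale` with Gower double-centering);
negative eigenvalues are dropped — no Cailliez/Lingoes correction — and
their total magnitude reported, with explained variance relative to the
positive spectrum.

`lefse_like()` scales abundances to 1e6 per sample so log10 effects land
on the conventional 2–5 scale, gates on a per-taxon Kruskal–Wallis test
(alpha 0.05), and computes a simplified one-feature LDA surrogate: the
log10 of the bootstrap mean (30 subsamples of two thirds of each group) of
half the absolute group-mean difference, floored at 1 before the log. A
taxon passes at p < alpha and effect ≥ 3. The canonical tool's
within-class covariance machinery and all-against-all subclass stage are
intentionally not replicated — the design here is a plain two-group
contrast, and accuracy is assessed against planted truth, not against the
canonical tool's numeric scores. Genus-level aggregation
(`aggregate_taxa()`) is available and recommended for lineage-annotated
tables.

## What the generators emulate — and what they do not

`simulate_ibd_cohorts()` emulates a multi-cohort meta-study: gene-wise
log2 baselines ~ Normal(7, 1.5²), additive per-batch per-gene offsets
~ Normal(0, batch_sd²), residual noise ~ Normal(0, noise_sd²), and a
planted two-subtype structure in which subtype 2 shifts half of the core
genes up by `effect_sd` and half down. The balanced up/down split is a
design decision: it prevents a single magnitude axis (or global scaling)
from trivially separating the subtypes. Defaults (3 batches × 200
samples, 2000 genes, 33 core genes, effect 1.0, batch 0.5, noise 1.0,
healthy fraction 0.25) are the package's study conditions; no effect-size
estimates exist for the real cohorts, so these are calibrated to be
realistic for moderate-effect bulk transcriptomics while keeping the
pipeline's planted-truth properties attainable, and are documented as
such. The healthy fraction exists because the first DEG pass contrasts
IBD against healthy controls.

`simulate_mixtures()` draws simplex fractions from a symmetric Dirichlet
and adds Gaussian noise to signature-matrix mixtures; the bundled
`synthetic_signature_matrix()` (8 cell types × 200 genes, marker-block
design) keeps deconvolution tests fast and well-conditioned; 22 types are
supported but not the default.

`simulate_response()` links non-response to the standardized score through
a logistic model; the default intercept (−0.85) places marginal
non-response near 30%, a typical primary non-response rate to anti-TNF
therapy.

`simulate_otu_counts()` draws baseline proportions from a symmetric
Dirichlet(5) over 200 taxa (a moderately even genus-level community),
plants signed fold changes on `n_diff` taxa — again half up, half down —
renormalizes, and samples Dirichlet-multinomial counts. The balanced
planting matters: raising 10% of community mass 4-fold and renormalizing
shifts *every* null taxon by ~23%, which a relative-abundance effect size
happily detects; balancing the planted mass keeps that compositional
spillover near 10%, below the discriminative cutoff for all but the most
abundant taxa. The overdispersion parameter is the inverse of the
per-sample Dirichlet concentration; the default 2e-4 yields ~20%
between-sample CV for a mean-abundance taxon at depth 50,000. Real mouse
cohorts are typically noisier and more skewed; passing tests on these
generators demonstrates correctness of the machinery, not expected power
on real data.

None of the generators emulate gene–gene correlation beyond the
subtype/batch structure, probe-level artifacts, library-size variation in
RNA-seq, or phylogenetic correlation among taxa.

## Problem sizes and determinism

The test suite and the acceptance script run the full chain at the study
conditions with 10 simulation seeds, using 20 NMF restarts per rank and a
500-iteration cap during rank selection (2000 iterations and 50 restarts
remain the function defaults); at these sizes the complete suite runs in
about a minute on one CPU. All generators and consensus procedures are
pure functions of (parameters, seed); per-stage and per-run streams are
derived deterministically from one master seed, and the pipeline's
manifest records the resolved configuration and input digests so a run can
be resumed or reproduced byte-identically.

## Known limitations

* Two-group contrasts only; no covariates, no multi-factor designs.
* The enrichment scorer is a rank-ECDF stand-in, not kernel GSVA; scores
  are comparable within one run only.
* The LDA effect size is a one-feature surrogate; cross-tool numeric
  agreement with canonical LEfSe is not a goal.
* PCoA drops negative eigenvalues rather than correcting them.
* Results on real GEO meta-cohorts (exact core-gene counts, cluster
  sizes, signature-gene lists) depend on the specific cohorts analyzed
  and are not desk-reproducible; the package's claims are property-level
  on planted ground truth.
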