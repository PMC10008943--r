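# ibddep

Depression-related molecular subtyping and scoring of inflammatory bowel
disease (IBD) transcriptomes.

Up to 40% of people with active IBD also suffer from anxiety or depression,
and the two conditions share immune and metabolic biology. `ibddep`
implements, as a tested and reusable pipeline, the analysis chain used to
dissect that overlap in bulk IBD transcriptomes:

1. **Core-gene derivation** — empirical-Bayes batch adjustment across
   cohorts, moderated-*t* differential expression between IBD and healthy
   samples (adjusted *p* < 0.05 and |log2FC| > 0.2), and intersection of
   the DEGs with a user-supplied depression-associated gene list to obtain
   a core-gene panel.
2. **NMF consensus subtyping** — the core-gene matrix *A* is repeatedly
   factorized as *A* ≈ *WH* with non-negative *W*, *H* (Brunet
   multiplicative updates minimizing the generalized Kullback–Leibler
   divergence); per-run sample assignments (argmax row of *H*) are
   aggregated into a consensus matrix; the rank is chosen by cophenetic,
   dispersion and silhouette diagnostics; the two clusters are oriented
   into a low-inflammatory `D.cluster1` and a pro-inflammatory
   `D.cluster2` by an inflammation marker panel.
3. **Characterization** — single-sample gene-set enrichment scores
   (weighted rank-ECDF scorer, for hallmark and metabolic collections),
   hypergeometric over-representation tests, immune-cell deconvolution
   against a signature matrix (non-negative least squares, or nu-SVR), and
   a Spearman correlation panel.
4. **D.score** — signature genes are derived between the subtypes, samples
   are scored by the sum of their first two principal-component scores
   (`D.score = PC1 + PC2`, oriented so that higher = more inflamed),
   stratified at the median into high/low groups, and associated with
   anti-TNF therapy response by a 2×2 chi-square test.
5. **Microbiome stage** — alpha diversity (observed, Chao1, ACE, Shannon),
   Bray–Curtis distances with PCoA ordination, and LEfSe-style
   differential-taxon discovery (Kruskal–Wallis gate, bootstrap log10
   effect size, discriminative cutoff 3).

Every stage has a synthetic-data generator with planted ground truth
(`simulate_ibd_cohorts()`, `simulate_mixtures()`, `simulate_response()`,
`simulate_otu_counts()`), so the whole pipeline is testable end to end
without any external download.

## Worked example

A synthetic three-cohort meta-study (3 batches × 200 samples, 2000 genes,
33 planted core genes):

```r
library(ibddep)

sim <- simulate_ibd_cohorts(seed = 7)
ann <- sim$annotations
x   <- combat_adjust(sim$expression, ann)

deg  <- moderated_ttest(x, ann$sample_id[ann$condition == "healthy"],
                        ann$sample_id[ann$condition == "IBD"])
core <- intersect_core_genes(select_degs(deg), depression_list)
length(core)
#> [1] 33

ibd <- ann$sample_id[ann$condition == "IBD"]
sel <- select_rank(to_nonnegative(x[core, ibd]), k_range = 2:4,
                   n_runs = 20, seed = 7, max_iter = 500)
sel$diagnostics
#>   k cophenetic dispersion silhouette
#> 1 2      0.976      0.734      0.909
#> 2 3      0.947      0.425      0.443
#> 3 4      0.893      0.364      0.277
```

The cophenetic coefficient peaks at k = 2; the consensus clusters are
oriented by an inflammation panel and scored:

```r
subtype <- assign_subtypes(sel$results$k2, x, inflammation_panel)
table(subtype)
#> D.cluster1 D.cluster2
#>        218        232

sig    <- signature_degs(x[, ibd], subtype)      # 38 signature genes
scores <- stratify(compute_dscore(x[sig, ibd], subtype))
#> mean D.score: D.cluster1 -2.65, D.cluster2 +2.49

resp  <- simulate_response(setNames(scores$dscore, scores$sample_id), seed = 7)
assoc <- response_association(setNames(scores$stratum, scores$sample_id), resp)
assoc$table
#>        non-responder responder
#>   high           135        90
#>   low             31       194
#> chi-square = 103.2, p = 2.97e-24, OR = 9.39
```

The pro-inflammatory subtype scores higher, and the high-`D.score` stratum
is strongly enriched for non-responders — the behaviour the score is
designed to quantify. `run_pipeline(default_config(seed = 1), "out/")`
executes the same chain end to end and writes TSV/JSON outputs plus a
run manifest.

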