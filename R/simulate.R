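# Synthetic-data generators with planted ground truth. All generators are
# pure functions of (params, seed): sub-streams are derived deterministically
# from the master seed so stages can be re-run independently.

derive_seed <- function(seed, stream) {
  # stable 31-bit stream derivation from (seed, stream name)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Simulate a multi-batch IBD meta-cohort with two planted subtypes
#'
#' Gene-wise baseline means are Normal(7, 1.5^2) on the log2 scale. IBD
#' samples are split evenly into subtypes 1 and 2; subtype 2 adds
#' `+effect_sd` to a random half of the `n_core` core genes and `-effect_sd`
#' to the other half (balanced so neither global scaling nor a pure
#' magnitude axis separates the subtypes). Each batch gets additive
#' per-gene offsets Normal(0, batch_sd^2); residual noise is
#' Normal(0, noise_sd^2). Healthy samples carry no subtype effect.
#'
#' @param n_per_batch Samples per batch.
#' @param n_batches Number of batches (cohorts).
#' @param n_genes Total genes.
#' @param n_core Planted core (subtype-defining) genes.
#' @param effect_sd Subtype effect size, log2 units.
#' @param batch_sd SD of per-batch per-gene offsets, log2 units.
#' @param noise_sd Residual noise SD, log2 units.
#' @param healthy_fraction Fraction of each batch that are healthy controls.
#' @param seed Master seed.
#' @return List with `expression` (genes x samples log2 matrix),
#'   `annotations` (data.frame: sample_id, batch, condition, disease,
#'   response) and `truth` (list: `samples` data.frame with true subtype,
#'   `core_genes` data.frame with planted effects).
#' @export
simulate_ibd_cohorts <- function(n_per_batch = 200, n_batches = 3,
                                 n_genes = 2000, n_core = 33,
                                 effect_sd = 1.0, batch_sd = 0.5,
                                 noise_sd = 1.0, healthy_fraction = 0.25,
                                 seed = 1) {
  stopifnot(n_per_batch >= 1, n_batches >= 1, n_genes >= 1, n_core >= 1,
            effect_sd >= 0, batch_sd >= 0, noise_sd >= 0,
            healthy_fraction >= 0, healthy_fraction < 1)
  if (n_core > n_genes) stop("n_core exceeds n_genes")
  set.seed(derive_seed(seed, "ibd_cohorts"))

  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  mu <- stats::rnorm(n_genes, mean = 7, sd = 1.5)

  core_idx <- sort(sample.int(n_genes, n_core))
  up <- sample(c(rep(TRUE, ceiling(n_core / 2)),
                 rep(FALSE, floor(n_core / 2))))
  core_effect <- ifelse(up, effect_sd, -effect_sd)

  n_total <- n_per_batch * n_batches
  batch <- rep(sprintf("batch%d", seq_len(n_batches)), each = n_per_batch)
  sample_id <- sprintf("%s_s%03d", batch,
                       unlist(lapply(seq_len(n_batches),
                                     function(b) seq_len(n_per_batch))))
  n_healthy <- round(healthy_fraction * n_per_batch)
  condition <- rep(c(rep("healthy", n_healthy),
                     rep("IBD", n_per_batch - n_healthy)), n_batches)
  subtype <- rep(NA_integer_, n_total)
  for (b in seq_len(n_batches)) {
    idx <- which(batch == sprintf("batch%d", b) & condition == "IBD")
    half <- floor(length(idx) / 2)
    st <- c(rep(1L, half), rep(2L, length(idx) - half))
    subtype[idx] <- sample(st)
  }
  disease <- ifelse(condition == "IBD",
                    ifelse(stats::runif(n_total) < 0.6, "UC", "CD"),
                    NA_character_)

  x <- matrix(mu, n_genes, n_total) +
    matrix(stats::rnorm(n_genes * n_total, sd = noise_sd), n_genes, n_total)
  batch_offsets <- matrix(stats::rnorm(n_genes * n_batches, sd = batch_sd),
                          n_genes, n_batches)
  for (b in seq_len(n_batches)) {
    cols <- which(batch == sprintf("batch%d", b))
    x[, cols] <- x[, cols] + batch_offsets[, b]
  }
  st2 <- which(!is.na(subtype) & subtype == 2L)
  x[core_idx, st2] <- x[core_idx, st2] + core_effect

  dimnames(x) <- list(gene_ids, sample_id)
  attr(x, "scale") <- "log2"
  ann <- data.frame(sample_id = sample_id, batch = batch,
                    condition = condition, disease = disease,
                    response = NA_character_, stringsAsFactors = FALSE)
  truth <- list(
    samples = data.frame(sample_id = sample_id, batch = batch,
                         condition = condition, subtype = subtype,
                         stringsAsFactors = FALSE),
    core_genes = data.frame(gene_id = gene_ids[core_idx],
                            effect = core_effect, stringsAsFactors = FALSE)
  )
  list(expression = x, annotations = ann, truth = truth)
}

#' Generate a synthetic cell-type signature matrix
#'
#' Each cell type gets a block of strongly expressed marker genes on a low
#' common background, giving a well-conditioned nonnegative signature. The
#' default 8 types x 200 genes keeps deconvolution tests fast; any number of
#' types (e.g. 22) is supported.
#'
#' @param n_cell_types Number of cell types.
#' @param n_genes Number of signature genes.
#' @param marker_strength Mean expression of a type's marker block (linear
#'   scale) relative to background 1.
#' @param seed Seed.
#' @return Nonnegative matrix genes x cell types.
#' @export
synthetic_signature_matrix <- function(n_cell_types = 8, n_genes = 200,
                                       marker_strength = 20, seed = 1) {
  stopifnot(n_cell_types >= 2, n_genes >= n_cell_types)
  set.seed(derive_seed(seed, "signature"))
  s <- matrix(stats::rgamma(n_genes * n_cell_types, shape = 2, rate = 2),
              n_genes, n_cell_types)
  block <- split(seq_len(n_genes),
                 cut(seq_len(n_genes), n_cell_types, labels = FALSE))
  for (k in seq_len(n_cell_types)) {
    s[block[[k]], k] <- s[block[[k]], k] +
      stats::rgamma(length(block[[k]]), shape = 4, rate = 4 / marker_strength)
  }
  dimnames(s) <- list(sprintf("sg%03d", seq_len(n_genes)),
                      sprintf("cell_type_%02d", seq_len(n_cell_types)))
  s
}

#' Simulate bulk mixtures of cell-type signature profiles
#'
#' Fractions are drawn from a symmetric Dirichlet; the mixture is
#' `signature %*% fractions` plus Gaussian noise, clipped at zero.
#'
#' @param signature Nonnegative genes x cell types matrix.
#' @param n_samples Number of mixtures.
#' @param dirichlet_alpha Symmetric Dirichlet concentration (> 0).
#' @param noise_sd Additive Gaussian noise SD (linear scale).
#' @param seed Seed.
#' @return List with `expression` (genes x samples) and `truth` (cell types x
#'   samples true fraction matrix, columns on the simplex).
#' @export
simulate_mixtures <- function(signature, n_samples, dirichlet_alpha = 1,
                              noise_sd = 0, seed = 1) {
  stopifnot(dirichlet_alpha > 0, n_samples >= 1, all(signature >= 0))
  set.seed(derive_seed(seed, "mixtures"))
  k <- ncol(signature)
  f <- rdirichlet(n_samples, rep(dirichlet_alpha, k))  # samples x k
  x <- signature %*% t(f) +
    matrix(stats::rnorm(nrow(signature) * n_samples, sd = noise_sd),
           nrow(signature), n_samples)
  x[x < 0] <- 0
  colnames(x) <- sprintf("mix%03d", seq_len(n_samples))
  truth <- t(f)
  dimnames(truth) <- list(colnames(signature), colnames(x))
  list(expression = x, truth = truth)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Simulate anti-TNF response labels linked to a depression score
#'
#' Non-response probability follows a logistic model on the standardized
#' score: `P(non-responder) = plogis(beta0 + beta1 * z)`. The default
#' `beta0` places marginal non-response near 30%, the commonly reported
#' anti-TNF primary non-response rate.
#'
#' @param dscores Numeric vector of per-sample scores.
#' @param beta0 Intercept on the logit scale.
#' @param beta1 Slope per SD of score.
#' @param seed Seed.
#' @return Character vector `responder`/`non-responder`, named by the names
#'   of `dscores` when present.
#' @export
simulate_response <- function(dscores, beta0 = -0.85, beta1 = 1.5, seed = 1) {
  stopifnot(all(is.finite(dscores)))
  set.seed(derive_seed(seed, "response"))
  z <- if (stats::sd(dscores) > 0) {
    (dscores - mean(dscores)) / stats::sd(dscores)
  } else {
    rep(0, length(dscores))
  }
  p_nr <- stats::plogis(beta0 + beta1 * z)
  lab <- ifelse(stats::runif(length(dscores)) < p_nr,
                "non-responder", "responder")
  names(lab) <- names(dscores)
  lab
}

#' Simulate an OTU count table with planted differential taxa
#'
#' Baseline taxon proportions are drawn from a symmetric Dirichlet
#' (`base_alpha`). Half of the `n_diff` planted taxa are shifted up by
#' `+log2fc` and half down by `-log2fc` in group 2 (balanced planting keeps
#' compositional spillover onto null taxa small), then proportions are
#' renormalized. Counts are multinomial at the requested depth; with
#' `overdispersion > 0` each sample's proportions are first resampled from a
#' Dirichlet with concentration `1/overdispersion` (Dirichlet-multinomial).
#'
#' @param n_taxa Number of taxa.
#' @param n_samples_per_group Samples per group (2 groups).
#' @param n_diff Number of planted differential taxa.
#' @param log2fc Planted log2 fold change magnitude.
#' @param depth Sequencing depth per sample (>= 100).
#' @param overdispersion Dirichlet-multinomial overdispersion (the inverse
#'   of the per-sample Dirichlet concentration); 0 gives plain multinomial
#'   sampling. The default 2e-4 puts the between-sample CV of a
#'   mean-abundance taxon near 20%.
#' @param base_alpha Symmetric Dirichlet concentration for baseline
#'   proportions.
#' @param seed Seed.
#' @return List with `otu` (an [otu_table()]), `groups` (character vector of
#'   `group1`/`group2` per sample) and `truth` (data.frame of planted taxa
#'   and signed log2 fold changes).
#' @export
simulate_otu_counts <- function(n_taxa = 200, n_samples_per_group = 10,
                                n_diff = 20, log2fc = 2, depth = 50000,
                                overdispersion = 2e-4, base_alpha = 5,
                                seed = 1) {
  stopifnot(n_diff <= n_taxa, depth >= 100, overdispersion >= 0,
            base_alpha > 0)
  set.seed(derive_seed(seed, "otu"))
  taxa <- sprintf("otu%04d", seq_len(n_taxa))
  lineage <- sprintf(
    "k__Bacteria;p__P%02d;c__C%02d;o__O%02d;f__F%03d;g__G%04d",
    (seq_len(n_taxa) - 1) %% 8 + 1, (seq_len(n_taxa) - 1) %% 16 + 1,
    (seq_len(n_taxa) - 1) %% 32 + 1, (seq_len(n_taxa) - 1) %% 64 + 1,
    seq_len(n_taxa))

  p1 <- as.numeric(rdirichlet(1, rep(base_alpha, n_taxa)))
  diff_idx <- sort(sample.int(n_taxa, n_diff))
  sign_up <- sample(c(rep(TRUE, ceiling(n_diff / 2)),
                      rep(FALSE, floor(n_diff / 2))))
  lfc <- ifelse(sign_up, log2fc, -log2fc)
  p2 <- p1
  p2[diff_idx] <- p2[diff_idx] * 2^lfc
  p2 <- p2 / sum(p2)

  n <- n_samples_per_group
  draw_group <- function(p, n) {
    vapply(seq_len(n), function(i) {
      pi <- if (overdispersion > 0) {
        as.numeric(rdirichlet(1, p / overdispersion))
      } else p
      stats::rmultinom(1, size = depth, prob = pi)[, 1]
    }, integer(n_taxa))
  }
  counts <- cbind(draw_group(p1, n), draw_group(p2, n))
  dimnames(counts) <- list(taxa, c(sprintf("g1_s%02d", seq_len(n)),
                                   sprintf("g2_s%02d", seq_len(n))))
  groups <- rep(c("group1", "group2"), each = n)
  names(groups) <- colnames(counts)
  list(otu = otu_table(counts, lineage), groups = groups,
       truth = data.frame(taxon_id = taxa[diff_idx], log2fc = lfc,
                          stringsAsFactors = FALSE))
}
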