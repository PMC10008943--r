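# 16S stage: alpha diversity, Bray-Curtis PCoA, and LEfSe-style
# differential-taxon discovery with an LDA-like effect-size cutoff.

otu_counts <- function(t) {
  if (inherits(t, "OtuTable")) t$counts else as.matrix(t)
}

#' Per-sample alpha diversity (observed, Chao1, ACE, Shannon)
#'
#' Shannon is in natural-log units over nonzero proportions. Chao1 uses the
#' bias-corrected form `S_obs + F1*(F1-1)/(2*(F2+1))` (singletons F1,
#' doubletons F2); ACE is the abundance-based coverage estimator with rare
#' cutoff 10. Samples whose taxa are all abundant reduce to the observed
#' richness for both estimators.
#'
#' @param t An [otu_table()] or integer taxa x samples matrix.
#' @return data.frame: `sample_id`, `observed`, `chao1`, `ace`, `shannon`.
#' @export
alpha_diversity <- function(t) {
  counts <- otu_counts(t)
  if (any(counts != floor(counts))) stop("counts must be integers")
  tc <- t(counts)                       # vegan wants samples in rows
  est <- vegan::estimateR(tc)           # S.obs, S.chao1, S.ACE
  obs <- est["S.obs", ]
  chao <- est["S.chao1", ]
  ace <- est["S.ACE", ]
  # no rare taxa (all counts > 10): coverage estimator degenerates to S_obs
  ace[!is.finite(ace)] <- obs[!is.finite(ace)]
  shannon <- vegan::diversity(tc, index = "shannon")
  data.frame(sample_id = colnames(counts), observed = unname(obs),
             chao1 = unname(chao), ace = unname(ace),
             shannon = unname(shannon),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classical scaling (principal coordinate analysis) of a distance matrix
#'
#' Gower double-centering and eigendecomposition; coordinates are
#' eigenvectors scaled by the square root of their eigenvalues. Negative
#' eigenvalues are dropped and their total magnitude reported; explained
#' variance fractions are relative to the positive eigenvalues.
#'
#' @param d A `dist` or symmetric distance matrix.
#' @param n_axes Number of axes requested.
#' @return List: `coordinates` (samples x axes), `explained` (fractions),
#'   `negative_eigenvalue_mass`.
#' @export
classical_pcoa <- function(d, n_axes = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  # cmdscale warns when fewer than k eigenvalues are positive; the
  # eigenvalue bookkeeping below handles that case explicitly
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))
  n_pos <- sum(pos)
  if (n_axes > n_pos) {
    warning("only ", n_pos, " positive eigenvalue(s); axes truncated")
    n_axes <- n_pos
  }
  coords <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(n_axes))
  list(coordinates = coords,
       explained = fit$eig[seq_len(n_axes)] / sum(fit$eig[pos]),
       negative_eigenvalue_mass = sum(abs(fit$eig[fit$eig < 0])))
}

#' Bray-Curtis distances and PCoA ordination
#'
#' Distances are computed on relative abundances:
#' `d(x, y) = sum |x - y| / sum (x + y)`.
#'
#' @param t An [otu_table()] or counts matrix with >= 3 samples.
#' @param n_axes Number of ordination axes (default 2).
#' @return List: `distance` (samples x samples matrix), `coordinates`,
#'   `explained`, `negative_eigenvalue_mass`.
#' @export
bray_curtis_pcoa <- function(t, n_axes = 2) {
  counts <- otu_counts(t)
  if (ncol(counts) < 3) stop("need at least 3 samples")
  rel <- sweep(counts, 2, colSums(counts), "/")
  d <- vegan::vegdist(t(rel), method = "bray")
  ord <- classical_pcoa(d, n_axes = n_axes)
  c(list(distance = as.matrix(d)), ord)
}

#' Aggregate an OTU table to a taxonomic rank
#'
#' Sums counts over taxa sharing the lineage prefix up to the requested
#' rank (kingdom to genus).
#'
#' @param otu An [otu_table()].
#' @param rank One of kingdom/phylum/class/order/family/genus.
#' @return An [otu_table()] at the requested rank.
#' @export
aggregate_taxa <- function(otu, rank = "genus") {
  ranks <- c(kingdom = 1, phylum = 2, class = 3, order = 4, family = 5,
             genus = 6)
  if (!rank %in% names(ranks)) stop("unknown rank: ", rank)
  depth <- ranks[[rank]]
  key <- vapply(strsplit(otu$lineage, ";", fixed = TRUE), function(parts) {
    paste(parts[seq_len(min(depth, length(parts)))], collapse = ";")
  }, "")
  agg <- rowsum(otu$counts, group = key)
  otu_table(agg, lineage = rownames(agg))
}

#' LEfSe-style differential-abundance discovery
#'
#' Abundances are scaled to 1e6 per sample (so log10 effect sizes land on
#' the conventional 2-5 scale). Per taxon: a Kruskal-Wallis test across the
#' two groups; taxa with `p < kw_alpha` get an effect size: the log10 of
#' the bootstrap mean (over `n_boot` subsamples of two thirds of each
#' group) of half the absolute difference in group means of the scaled
#' abundance, floored at 1 before the log. A taxon passes when
#' `p < kw_alpha` and the effect reaches `lda_cutoff`.
#'
#' @param t An [otu_table()] or counts matrix.
#' @param groups Two-group character/factor vector, one entry per sample
#'   (each group >= 3 samples).
#' @param kw_alpha Kruskal-Wallis alpha (default 0.05).
#' @param lda_cutoff log10 effect-size cutoff (default 3, the conventional
#'   discriminative-feature threshold).
#' @param n_boot Bootstrap resamples (default 30).
#' @param seed Seed for the bootstrap.
#' @return data.frame: `taxon_id`, `kw_p`, `enriched`, `lda`, `pass`.
#' @export
lefse_like <- function(t, groups, kw_alpha = 0.05, lda_cutoff = 3.0,
                       n_boot = 30, seed = 1) {
  counts <- otu_counts(t)
  groups <- factor(groups)
  stopifnot(length(groups) == ncol(counts))
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 3)) stop("each group needs >= 3 samples")
  set.seed(derive_seed(seed, "lefse_boot"))

  scaled <- sweep(counts, 2, colSums(counts), "/") * 1e6
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  m1 <- max(2L, floor(2 / 3 * length(i1)))
  m2 <- max(2L, floor(2 / 3 * length(i2)))

  rows <- lapply(seq_len(nrow(scaled)), function(g) {
    v <- scaled[g, ]
    if (all(v == 0)) return(NULL)                 # absent everywhere: skip
    kw <- suppressWarnings(stats::kruskal.test(v, groups))$p.value
    if (is.na(kw)) kw <- 1
    enriched <- if (mean(v[i1]) >= mean(v[i2])) levels(groups)[1] else
      levels(groups)[2]
    lda <- NA_real_
    if (kw < kw_alpha) {
      diffs <- vapply(seq_len(n_boot), function(b) {
        s1 <- sample(i1, m1); s2 <- sample(i2, m2)
        abs(mean(v[s1]) - mean(v[s2])) / 2
      }, 0)
      lda <- log10(max(1, mean(diffs)))
    }
    data.frame(taxon_id = rownames(scaled)[g], kw_p = kw,
               enriched = enriched, lda = lda,
               pass = !is.na(lda) && kw < kw_alpha && lda >= lda_cutoff,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(taxon_id = character(), kw_p = numeric(),
                      enriched = character(), lda = numeric(),
                      pass = logical(), stringsAsFactors = FALSE)
  }
  row.names(out) <- NULL
  out
}
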