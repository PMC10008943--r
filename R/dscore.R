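# Depression signature genes, gene.cluster consensus grouping, the D.score
# (sum of the first two PC sample scores), stratification and association
# tests.

#' Derive depression signature genes between the two subtypes
#'
#' Moderated-t contrast of D.cluster2 versus D.cluster1 followed by the
#' same threshold filter as the cohort-level pass.
#'
#' @param x Genes x samples log2 matrix.
#' @param subtype_labels Character vector (`D.cluster1`/`D.cluster2`) named
#'   by sample.
#' @param p_adj_max,abs_lfc_min Thresholds passed to [select_degs()].
#' @return Character vector of signature gene ids.
#' @export
signature_degs <- function(x, subtype_labels, p_adj_max = 0.05,
                           abs_lfc_min = 0.2) {
  g1 <- names(subtype_labels)[subtype_labels == "D.cluster1"]
  g2 <- names(subtype_labels)[subtype_labels == "D.cluster2"]
  if (!length(g1) || !length(g2)) stop("both subtypes must be represented")
  deg <- moderated_ttest(x, g1, g2)
  select_degs(deg, p_adj_max = p_adj_max, abs_lfc_min = abs_lfc_min)
}

# k-means++ seeding: first center uniform, later centers with probability
# proportional to squared distance to the nearest chosen center
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    probs <- d2 / sum(d2)
    centers[i + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((x - matrix(x[centers[i + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  x[centers, , drop = FALSE]
}

kmeans_restarts <- function(x, k, n_restart = 10) {
  best <- NULL
  for (r in seq_len(n_restart)) {
    km <- tryCatch(
      stats::kmeans(x, centers = kmeanspp_centers(x, k), iter.max = 50),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss)) {
      best <- km
    }
  }
  best
}

#' Consensus k-means grouping of samples on the signature genes
#'
#' Resampling consensus clustering: each resample draws a fraction of the
#' samples, k-means (k-means++ seeding, 10 restarts) assigns them, and
#' co-assignment frequencies (conditional on co-sampling) are aggregated.
#' Final labels come from an average-linkage hierarchical cut of
#' `1 - consensus`. When an inflammation panel is given, the cluster with
#' the higher mean panel expression is named `gene.cluster2`.
#'
#' @param x_sig Signature-genes x samples log2 matrix (>= 10 genes,
#'   >= 10 samples).
#' @param k Number of clusters; must be 2.
#' @param n_resample Number of resamples (default 100).
#' @param subsample Fraction of samples drawn per resample (default 0.8).
#' @param seed Seed.
#' @param inflammation_panel Optional character vector used to orient the
#'   cluster names.
#' @param x Optional full expression matrix for panel orientation (defaults
#'   to `x_sig`).
#' @return Character vector (`gene.cluster1`/`gene.cluster2`) named by
#'   sample; attribute `consensus` carries the consensus matrix.
#' @export
gene_cluster_consensus <- function(x_sig, k = 2, n_resample = 100,
                                   subsample = 0.8, seed = 1,
                                   inflammation_panel = NULL, x = NULL) {
  if (k != 2) stop("gene.cluster grouping is defined for k = 2")
  if (nrow(x_sig) < 10 || ncol(x_sig) < 10) {
    stop("need >= 10 signature genes and >= 10 samples")
  }
  set.seed(derive_seed(seed, "gene_cluster"))
  xs <- t(scale(t(x_sig)))          # gene-wise z-scores
  xs[is.na(xs)] <- 0                # constant genes carry no information
  dat <- t(xs)                      # samples x genes
  n <- nrow(dat)
  co <- matrix(0, n, n); tog <- matrix(0, n, n)
  m <- max(2L, ceiling(subsample * n))
  for (b in seq_len(n_resample)) {
    idx <- sample.int(n, m)
    km <- kmeans_restarts(dat[idx, , drop = FALSE], k)
    if (is.null(km)) next
    ind <- matrix(0, m, k)
    ind[cbind(seq_len(m), km$cluster)] <- 1
    co[idx, idx] <- co[idx, idx] + tcrossprod(ind)
    tog[idx, idx] <- tog[idx, idx] + 1
  }
  cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
  diag(cons) <- 1
  cons <- (cons + t(cons)) / 2
  dimnames(cons) <- list(colnames(x_sig), colnames(x_sig))
  labels <- stats::cutree(stats::hclust(stats::as.dist(1 - cons),
                                        method = "average"), k = k)
  inflamed <- 2L
  if (!is.null(inflammation_panel)) {
    ref <- if (is.null(x)) x_sig else x
    panel <- intersect(inflammation_panel, rownames(ref))
    if (length(panel)) {
      pm <- colMeans(ref[panel, colnames(x_sig), drop = FALSE])
      inflamed <- if (mean(pm[labels == 2]) >= mean(pm[labels == 1])) 2L else 1L
    }
  }
  out <- ifelse(labels == inflamed, "gene.cluster2", "gene.cluster1")
  names(out) <- colnames(x_sig)
  attr(out, "consensus") <- cons
  out
}

#' Compute the per-sample depression score (D.score)
#'
#' Signature genes are standardized (mean 0, SD 1 across samples) and PCA
#' is run over samples. The first two principal-component sample scores are
#' extracted; each PC's sign is flipped, if needed, so that the mean score
#' of the inflammatory cluster (`D.cluster2`) exceeds that of `D.cluster1`
#' (higher score = more inflammation). The D.score is the per-sample sum
#' `PC1 + PC2`.
#'
#' @param x_sig Signature-genes x samples log2 matrix (>= 3 genes, >= 3
#'   samples, non-constant).
#' @param orient_against Character vector (`D.cluster1`/`D.cluster2`) named
#'   by sample, used only to orient the PC signs.
#' @return data.frame: `sample_id`, `pc1`, `pc2`, `dscore`, with attributes
#'   `orientation` (the two signs) and `signature_genes`.
#' @export
compute_dscore <- function(x_sig, orient_against) {
  stopifnot(nrow(x_sig) >= 3, ncol(x_sig) >= 3)
  sds <- apply(x_sig, 1, stats::sd)
  if (all(sds == 0)) stop("constant signature matrix; PCA undefined")
  xz <- (x_sig - rowMeans(x_sig)) / ifelse(sds > 0, sds, 1)
  pc <- stats::prcomp(t(xz), center = FALSE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12) {
    stop("fewer than 2 non-degenerate principal components")
  }
  scores <- pc$x[, 1:2, drop = FALSE]
  labs <- orient_against[colnames(x_sig)]
  c1 <- labs == "D.cluster1"; c2 <- labs == "D.cluster2"
  signs <- c(1, 1)
  for (i in 1:2) {
    if (mean(scores[c2, i]) < mean(scores[c1, i])) {
      signs[i] <- -1
      scores[, i] <- -scores[, i]
    }
  }
  out <- data.frame(sample_id = colnames(x_sig), pc1 = scores[, 1],
                    pc2 = scores[, 2], dscore = scores[, 1] + scores[, 2],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "orientation") <- signs
  attr(out, "signature_genes") <- rownames(x_sig)
  out
}

#' Stratify samples into high/low D.score groups
#'
#' Samples with D.score strictly above the cut point go to the `high`
#' stratum, the rest to `low`. The default cut is the median.
#'
#' @param scores A [compute_dscore()] table.
#' @param rule `"median"` or a numeric threshold.
#' @return The table with an added `stratum` column.
#' @export
stratify <- function(scores, rule = "median") {
  stopifnot(nrow(scores) >= 2)
  cut_at <- if (identical(rule, "median")) {
    stats::median(scores$dscore)
  } else if (is.numeric(rule)) rule else stop("unknown stratification rule")
  if (all(scores$dscore == scores$dscore[1])) {
    warning("all D.scores equal; every sample assigned to the low stratum")
  }
  scores$stratum <- ifelse(scores$dscore > cut_at, "high", "low")
  scores
}

#' Association between D.score strata and therapy response
#'
#' Pearson chi-square test (no continuity correction, df = 1) on the
#' 2x2 stratum x response table, with the odds ratio of non-response in
#' the high versus low stratum (Haldane 0.5 correction when a cell is 0).
#' Degenerate tables (a missing stratum or response class) are returned
#' without a test.
#'
#' @param strata Character vector `high`/`low` (or a prebuilt 2x2 matrix,
#'   in which case `response` is ignored).
#' @param response Character vector `responder`/`non-responder`, same
#'   order/names as `strata`.
#' @return List: `table`, `statistic`, `p_value`, `odds_ratio`,
#'   `haldane_corrected`.
#' @export
response_association <- function(strata, response = NULL) {
  if (is.matrix(strata)) {
    tab <- strata
  } else {
    keep <- !is.na(strata) & !is.na(response)
    tab <- table(factor(strata[keep], levels = c("high", "low")),
                 factor(response[keep],
                        levels = c("non-responder", "responder")))
    tab <- unclass(tab)
  }
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  stat <- p <- NA_real_
  if (!degenerate) {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    stat <- unname(ct$statistic); p <- ct$p.value
  }
  haldane <- any(tab == 0)
  tab_or <- if (haldane) tab + 0.5 else tab
  or <- (tab_or[1, 1] * tab_or[2, 2]) / (tab_or[1, 2] * tab_or[2, 1])
  list(table = tab, statistic = stat, p_value = p, odds_ratio = unname(or),
       haldane_corrected = haldane)
}

#' Compare a marker-gene panel between two groups
#'
#' Per-gene two-sided rank-sum (default) or t test, BH adjustment across
#' the panel, direction as the sign of the median difference (group 2 minus
#' group 1), and significance bins `ns`/`*`/`**`/`***`/`****` at adjusted p
#' thresholds 0.05 / 0.01 / 0.001 / 0.0001.
#'
#' @param x Genes x samples matrix.
#' @param groups Two-level factor (or character) named by sample; the
#'   second level is the reference direction "group 2".
#' @param panel Character vector of marker genes; panel genes absent from
#'   `x` are reported in the `skipped` element.
#' @param test `"wilcoxon"` (default) or `"ttest"`.
#' @return List: `results` (data.frame gene/direction/p/p_adj/signif),
#'   `skipped`.
#' @export
marker_compare <- function(x, groups, panel, test = c("wilcoxon", "ttest")) {
  test <- match.arg(test)
  groups <- factor(groups[colnames(x)])
  if (nlevels(groups) != 2) stop("exactly two groups required")
  skipped <- setdiff(panel, rownames(x))
  panel <- intersect(panel, rownames(x))
  if (!length(panel)) {
    return(list(results = data.frame(), skipped = skipped))
  }
  i1 <- which(groups == levels(groups)[1])
  i2 <- which(groups == levels(groups)[2])
  res <- do.call(rbind, lapply(panel, function(g) {
    v1 <- x[g, i1]; v2 <- x[g, i2]
    p <- if (test == "wilcoxon") {
      suppressWarnings(stats::wilcox.test(v2, v1)$p.value)
    } else {
      stats::t.test(v2, v1)$p.value
    }
    if (is.na(p)) p <- 1   # identical constant groups
    data.frame(gene = g,
               direction = sign(stats::median(v2) - stats::median(v1)),
               p = p, stringsAsFactors = FALSE)
  }))
  res$p_adj <- stats::p.adjust(res$p, method = "BH")
  res$signif <- cut(res$p_adj, breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
                    labels = c("****", "***", "**", "*", "ns"))
  res$signif <- as.character(res$signif)
  list(results = res, skipped = skipped)
}
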