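# Single-sample gene-set enrichment, over-representation tests, immune
# deconvolution against a signature matrix, and the Spearman panel.

#' Single-sample gene-set enrichment scores (weighted rank ECDF)
#'
#' For each sample, genes are ranked by expression (descending). A set's
#' enrichment score is the sum over the ranked list of the difference
#' between the weighted in-set ECDF (weights = rank statistic to the power
#' `alpha`, normalized within the set) and the unweighted out-of-set ECDF.
#' Because weights are rank statistics, scores are invariant to any
#' strictly monotone transform of a sample's expression. With
#' `normalize = TRUE` the whole score matrix is divided by its range.
#'
#' Genes in a set but absent from the matrix are dropped with a warning;
#' sets with no gene present get `NA` scores and are flagged in the
#' `undefined_sets` attribute.
#'
#' @param x Genes x samples expression matrix.
#' @param sets Named list of character vectors (see [read_gmt()]).
#' @param alpha Nonnegative weight exponent (default 0.25).
#' @param normalize Divide scores by the overall score range.
#' @return Samples x sets matrix of scores; attributes `alpha` and
#'   `undefined_sets`.
#' @export
ssgsea_scores <- function(x, sets, alpha = 0.25, normalize = TRUE) {
  if (alpha < 0) stop("alpha must be nonnegative")
  stopifnot(is.matrix(x), length(sets) >= 1, !is.null(names(sets)))
  n_genes <- nrow(x)
  present <- lapply(sets, function(s) intersect(s, rownames(x)))
  dropped <- vapply(sets, length, 1L) - vapply(present, length, 1L)
  if (any(dropped > 0)) {
    warning(sum(dropped), " set gene(s) absent from the matrix were dropped")
  }
  undefined <- names(sets)[vapply(present, length, 1L) == 0L]

  scores <- matrix(NA_real_, ncol(x), length(sets),
                   dimnames = list(colnames(x), names(sets)))
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "average")     # high expression = high rank
    ord <- order(x[, j], decreasing = TRUE)
    w <- r[ord]^alpha
    for (s in seq_along(sets)) {
      genes <- present[[s]]
      if (!length(genes)) next
      inset <- rownames(x)[ord] %in% genes
      m <- sum(inset)
      p_in <- cumsum(w * inset) / sum(w[inset])
      p_out <- cumsum(!inset) / (n_genes - m)
      scores[j, s] <- sum(p_in - p_out)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  attr(scores, "alpha") <- alpha
  attr(scores, "undefined_sets") <- undefined
  scores
}

#' Over-representation analysis by the hypergeometric test
#'
#' One-sided upper-tail hypergeometric p per set (enrichment of the gene
#' list in the set, within the universe), BH-adjusted across sets. Sets are
#' intersected with the universe first; sets disjoint from the universe are
#' dropped with a warning.
#'
#' @param gene_list Character vector, a subset of `universe`.
#' @param universe Character vector of all assayed genes.
#' @param sets Named list of character vectors.
#' @return data.frame: `set`, `set_size`, `overlap`, `p`, `q`.
#' @export
ora_enrichment <- function(gene_list, universe, sets) {
  gene_list <- unique(gene_list); universe <- unique(universe)
  if (!length(gene_list)) stop("empty gene list")
  if (!length(universe)) stop("empty universe")
  out <- setdiff(gene_list, universe)
  if (length(out)) stop("gene list not contained in universe: ",
                        paste(utils::head(out), collapse = ", "))
  sets_u <- lapply(sets, intersect, universe)
  empty <- vapply(sets_u, length, 1L) == 0L
  if (any(empty)) {
    warning(sum(empty), " set(s) disjoint from the universe were dropped")
    sets_u <- sets_u[!empty]
  }
  if (!length(sets_u)) stop("no gene set overlaps the universe")
  n_u <- length(universe); n_l <- length(gene_list)
  kk <- vapply(sets_u, function(s) length(intersect(s, gene_list)), 1L)
  sz <- vapply(sets_u, length, 1L)
  p <- stats::phyper(kk - 1, sz, n_u - sz, n_l, lower.tail = FALSE)
  data.frame(set = names(sets_u), set_size = sz, overlap = kk, p = p,
             q = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Deconvolve bulk mixtures against a cell-type signature matrix
#'
#' Features are restricted to the signature genes and each gene is scaled
#' by its signature-matrix SD so all genes contribute comparably (centering
#' across cell types is deliberately avoided: it would make the scaled
#' signature columns sum to zero, losing a rank and leaving fractions
#' unidentifiable). A noiseless mixture of the signature columns is then
#' recovered exactly. Per sample, cell-type
#' coefficients are obtained by nonnegative least squares (default) or
#' linear nu-support-vector regression (nu in 0.25/0.5/0.75, best residual
#' kept, negative coefficients clipped); fractions are renormalized to the
#' simplex. Optional permutation p: the fraction of gene-shuffled fits
#' whose reconstruction correlation reaches the observed one.
#'
#' @param x_mix Genes x samples mixture matrix.
#' @param s Nonnegative genes x cell-types signature matrix, full column
#'   rank on the shared genes.
#' @param mode `"nnls"` (default) or `"nusvr"`.
#' @param n_perm Number of permutations for the per-sample p (0 = skip).
#' @param seed Seed for permutations.
#' @return List: `fractions` (samples x cell types, rows on the simplex),
#'   `rmse` (per-sample fit residual on the z-scale), `p_value` (per-sample
#'   permutation p or `NA`).
#' @export
deconvolve <- function(x_mix, s, mode = c("nnls", "nusvr"), n_perm = 0,
                       seed = 1) {
  mode <- match.arg(mode)
  genes <- intersect(rownames(s), rownames(x_mix))
  k <- ncol(s)
  if (length(genes) < k) stop("fewer shared signature genes than cell types")
  s <- s[genes, , drop = FALSE]
  x <- x_mix[genes, , drop = FALSE]
  sd_g <- apply(s, 1, stats::sd)
  keep <- sd_g > 0
  s_z <- s[keep, , drop = FALSE] / sd_g[keep]
  x_z <- x[keep, , drop = FALSE] / sd_g[keep]
  qrs <- qr(s_z)
  if (qrs$rank < k) {
    coll <- colnames(s)[qrs$pivot[(qrs$rank + 1):k]]
    stop("signature matrix is rank deficient; collinear column(s): ",
         paste(coll, collapse = ", "))
  }

  solve_one <- function(y) {
    if (mode == "nnls") {
      f <- pracma::lsqnonneg(s_z, y)$x
    } else {
      best <- NULL; best_rmse <- Inf
      for (nu in c(0.25, 0.5, 0.75)) {
        fit <- e1071::svm(x = s_z, y = y, type = "nu-regression",
                          kernel = "linear", nu = nu, scale = FALSE)
        co <- as.numeric(t(fit$coefs) %*% fit$SV)
        co[co < 0] <- 0
        rm_ <- sqrt(mean((y - s_z %*% co)^2))
        if (rm_ < best_rmse) { best <- co; best_rmse <- rm_ }
      }
      f <- best
    }
    f
  }

  n <- ncol(x_z)
  fractions <- matrix(0, n, k, dimnames = list(colnames(x_z), colnames(s)))
  rmse <- numeric(n); pval <- rep(NA_real_, n)
  set.seed(derive_seed(seed, "deconvolve_perm"))
  for (j in seq_len(n)) {
    y <- x_z[, j]
    f <- solve_one(y)
    fit_y <- as.numeric(s_z %*% f)
    rmse[j] <- sqrt(mean((y - fit_y)^2))
    tot <- sum(f)
    fractions[j, ] <- if (tot > 0) f / tot else rep(1 / k, k)
    if (n_perm > 0) {
      obs <- suppressWarnings(stats::cor(fit_y, y))
      if (is.na(obs)) obs <- 0
      perm_r <- vapply(seq_len(n_perm), function(b) {
        yp <- sample(y)
        fp <- solve_one(yp)
        r <- suppressWarnings(stats::cor(as.numeric(s_z %*% fp), yp))
        if (is.na(r)) 0 else r
      }, 0)
      pval[j] <- mean(perm_r >= obs)
    }
  }
  names(rmse) <- colnames(x_z); names(pval) <- colnames(x_z)
  list(fractions = fractions, rmse = rmse, p_value = pval)
}

#' Spearman correlation panel with BH-adjusted p-values
#'
#' Pairwise Spearman rho (average ranks on ties) between the columns of two
#' score tables over paired samples, with two-sided p-values from the t
#' approximation and BH adjustment across all pairs. Constant columns give
#' `NA` with the reason recorded in the `undefined` attribute.
#'
#' @param scores_a,scores_b Numeric matrices/data.frames, samples in rows
#'   (same row order), n >= 5.
#' @return List: `rho`, `p`, `p_adj` (matrices columns of `scores_a` x
#'   columns of `scores_b`).
#' @export
spearman_panel <- function(scores_a, scores_b) {
  a <- as.matrix(scores_a); b <- as.matrix(scores_b)
  stopifnot(nrow(a) == nrow(b))
  n <- nrow(a)
  if (n < 5) stop("need at least 5 paired samples")
  const_a <- apply(a, 2, function(v) stats::sd(v) == 0)
  const_b <- apply(b, 2, function(v) stats::sd(v) == 0)
  rho <- suppressWarnings(stats::cor(a, b, method = "spearman"))
  rho[const_a, ] <- NA; rho[, const_b] <- NA
  tt <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p_adj <- matrix(stats::p.adjust(p, method = "BH"), nrow(p), ncol(p),
                  dimnames = dimnames(p))
  undefined <- c(
    if (any(const_a)) paste0("constant column in scores_a: ",
                             paste(colnames(a)[const_a], collapse = ", ")),
    if (any(const_b)) paste0("constant column in scores_b: ",
                             paste(colnames(b)[const_b], collapse = ", ")))
  structure(list(rho = rho, p = p, p_adj = p_adj), undefined = undefined)
}
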