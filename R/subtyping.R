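# NMF consensus clustering of the core-gene matrix: Brunet KL-divergence
# factorization (Rcpp kernel), consensus aggregation over restarts, rank
# diagnostics (cophenetic, dispersion, silhouette) and subtype orientation.

#' Map a log-scale expression matrix to a nonnegative matrix
#'
#' @param x Numeric matrix.
#' @param mode `"offset"` subtracts the global minimum when it is negative;
#'   `"posneg"` stacks `max(x, 0)` and `max(-x, 0)` as separate rows;
#'   `"none"` validates that `x` is already nonnegative.
#' @return A nonnegative matrix.
#' @export
to_nonnegative <- function(x, mode = c("offset", "posneg", "none")) {
  mode <- match.arg(mode)
  switch(mode,
    offset = {
      mn <- min(x)
      if (mn < 0) x - mn else x
    },
    posneg = {
      up <- pmax(x, 0); dn <- pmax(-x, 0)
      rownames(up) <- paste0(rownames(x), "_pos")
      rownames(dn) <- paste0(rownames(x), "_neg")
      rbind(up, dn)
    },
    none = {
      if (any(x < 0)) stop("matrix has negative entries; mode='none'")
      x
    })
}

#' Single NMF factorization with Brunet KL-divergence updates
#'
#' Multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence D(A || WH). Iteration stops when the relative divergence
#' change over a 10-iteration window falls below `tol`, or at `max_iter`.
#' The scale ambiguity is resolved by normalizing the columns of W to unit
#' sum (compensated in H).
#'
#' @param a Nonnegative matrix with no all-zero row or column.
#' @param k Factorization rank, `1 <= k < min(dim(a))`.
#' @param seed Seed for the random uniform initialization.
#' @param max_iter Maximum iterations (default 2000).
#' @param tol Relative convergence tolerance (default 1e-6).
#' @return An `NmfFit` list: `W`, `H`, `trace` (KL divergence per iteration,
#'   non-increasing), `iterations`, `converged`, `seed`.
#' @export
nmf_factorize <- function(a, k, seed = 1, max_iter = 2000, tol = 1e-6) {
  stopifnot(is.matrix(a), is.numeric(a))
  if (any(a < 0)) stop("negative entry in input matrix")
  zr <- which(rowSums(a) == 0); zc <- which(colSums(a) == 0)
  if (length(zr)) stop("all-zero row(s): ", paste(utils::head(zr), collapse = ", "))
  if (length(zc)) stop("all-zero column(s): ", paste(utils::head(zc), collapse = ", "))
  if (k < 1 || k >= min(dim(a))) stop("k must satisfy 1 <= k < min(dim(a))")
  set.seed(seed)
  sc <- sqrt(mean(a) / k)
  w0 <- matrix(stats::runif(nrow(a) * k, min = 1e-4, max = 1), nrow(a), k) * sc
  h0 <- matrix(stats::runif(k * ncol(a), min = 1e-4, max = 1), k, ncol(a)) * sc
  fit <- nmf_kl_cpp(a, w0, h0, as.integer(max_iter), tol)
  cs <- colSums(fit$W)
  fit$W <- sweep(fit$W, 2, cs, "/")
  fit$H <- sweep(fit$H, 1, cs, "*")
  dimnames(fit$W) <- list(rownames(a), NULL)
  dimnames(fit$H) <- list(NULL, colnames(a))
  fit$seed <- seed
  class(fit) <- "NmfFit"
  fit
}

# hard sample assignment: argmax row of H, lowest index on ties
nmf_labels <- function(h) {
  max.col(t(h), ties.method = "first")
}

#' NMF consensus clustering at a fixed rank
#'
#' Repeats [nmf_factorize()] `n_runs` times from different seeded
#' initializations; per run each sample is assigned to the argmax row of H
#' (ties to the lowest index); binary connectivity matrices are averaged
#' into the consensus matrix C. Final labels come from average-linkage
#' hierarchical clustering of `1 - C` cut at `k`, so labels reflect the
#' consensus rather than any single run. Diagnostics: the cophenetic
#' coefficient (Pearson correlation between the dendrogram's cophenetic
#' distances and the off-diagonal of `1 - C`), dispersion (mean of
#' `4*(C_ij - 1/2)^2` over off-diagonal entries; 1 for binary consensus, 0
#' for an all-ambiguous matrix) and mean silhouette width on distance
#' `1 - C`.
#'
#' @param a Nonnegative matrix (features x samples).
#' @param k Number of clusters.
#' @param n_runs Number of restarts (>= 2, default 50).
#' @param seed Master seed; per-run seeds are derived deterministically.
#' @param max_iter,tol Passed to [nmf_factorize()].
#' @return A `ConsensusResult` list: `k`, `consensus`, `labels` (integer,
#'   named by sample), `cophenetic`, `dispersion`, `silhouette`, `n_runs`.
#' @export
consensus_cluster <- function(a, k, n_runs = 50, seed = 1,
                              max_iter = 2000, tol = 1e-6) {
  stopifnot(n_runs >= 2)
  n <- ncol(a)
  cmat <- matrix(0, n, n)
  for (r in seq_len(n_runs)) {
    fit <- nmf_factorize(a, k,
                         seed = derive_seed(seed, sprintf("nmf_k%d_run%d", k, r)),
                         max_iter = max_iter, tol = tol)
    lab <- nmf_labels(fit$H)
    ind <- matrix(0, n, k)
    ind[cbind(seq_len(n), lab)] <- 1
    cmat <- cmat + tcrossprod(ind)
  }
  cmat <- cmat / n_runs
  cmat <- (cmat + t(cmat)) / 2
  diag(cmat) <- 1
  dimnames(cmat) <- list(colnames(a), colnames(a))

  m <- consensus_metrics(cmat, k)
  structure(list(k = k, consensus = cmat, labels = m$labels,
                 cophenetic = m$cophenetic, dispersion = m$dispersion,
                 silhouette = m$silhouette, n_runs = n_runs),
            class = "ConsensusResult")
}

# labels and rank diagnostics from a consensus matrix
consensus_metrics <- function(cmat, k) {
  d <- stats::as.dist(1 - cmat)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  coph <- suppressWarnings(stats::cor(stats::cophenetic(hc), d))
  if (is.na(coph)) coph <- 1  # degenerate: all distances equal
  off <- cmat[upper.tri(cmat)]
  dispersion <- mean(4 * (off - 0.5)^2)
  sil <- if (length(unique(labels)) > 1) {
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  } else NA_real_
  list(labels = labels, cophenetic = coph, dispersion = dispersion,
       silhouette = sil)
}

#' Select the factorization rank by consensus diagnostics
#'
#' Runs [consensus_cluster()] for each candidate rank and returns the
#' smallest k maximizing the cophenetic coefficient, with dispersion and
#' silhouette as lexicographic tie-breakers (in that order). When the best
#' cophenetic coefficient is below 0.9 the result carries a low-confidence
#' flag (no rank shows stable consensus).
#'
#' @param a Nonnegative matrix (features x samples).
#' @param k_range Integer vector of candidate ranks (default 2:6).
#' @param n_runs Restarts per rank.
#' @param seed Master seed.
#' @param max_iter,tol Passed down to the factorizations.
#' @return List: `k` (selected rank), `diagnostics` (data.frame of k,
#'   cophenetic, dispersion, silhouette), `results` (named list of
#'   `ConsensusResult` per rank), `low_confidence`.
#' @export
select_rank <- function(a, k_range = 2:6, n_runs = 50, seed = 1,
                        max_iter = 2000, tol = 1e-6) {
  stopifnot(all(k_range >= 1), all(k_range < min(dim(a))))
  results <- lapply(k_range, function(k) {
    consensus_cluster(a, k, n_runs = n_runs, seed = seed,
                      max_iter = max_iter, tol = tol)
  })
  names(results) <- paste0("k", k_range)
  diag_df <- data.frame(
    k = k_range,
    cophenetic = vapply(results, `[[`, 0, "cophenetic"),
    dispersion = vapply(results, `[[`, 0, "dispersion"),
    silhouette = vapply(results, `[[`, 0, "silhouette"),
    row.names = NULL)
  ord <- order(-diag_df$cophenetic, -diag_df$dispersion,
               -diag_df$silhouette, diag_df$k)
  kstar <- diag_df$k[ord[1]]
  list(k = kstar, diagnostics = diag_df, results = results,
       low_confidence = max(diag_df$cophenetic) < 0.9)
}

#' Orient two consensus clusters into D.cluster1 / D.cluster2
#'
#' The cluster with the higher mean expression of the inflammation panel is
#' labeled `D.cluster2` (the pro-inflammatory, depression-like subtype);
#' the other becomes `D.cluster1`. Deterministic and invariant to the
#' arbitrary cluster indices of the consensus step.
#'
#' @param result A `ConsensusResult` with `k = 2`.
#' @param x Genes x samples log2 expression matrix covering the same
#'   samples.
#' @param inflammation_panel Character vector of pro-inflammatory marker
#'   genes present in `x`.
#' @return Character vector `D.cluster1`/`D.cluster2` named by sample.
#' @export
assign_subtypes <- function(result, x, inflammation_panel) {
  if (result$k != 2) stop("subtype orientation requires k = 2")
  if (!length(inflammation_panel)) stop("empty inflammation panel")
  panel <- intersect(inflammation_panel, rownames(x))
  if (!length(panel)) stop("no inflammation panel gene present in the matrix")
  labs <- result$labels
  samples <- names(labs)
  panel_mean <- colMeans(x[panel, samples, drop = FALSE])
  m1 <- mean(panel_mean[labs == 1]); m2 <- mean(panel_mean[labs == 2])
  inflamed <- if (m2 >= m1) 2L else 1L
  out <- ifelse(labs == inflamed, "D.cluster2", "D.cluster1")
  names(out) <- samples
  out
}
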