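# Batch adjustment, moderated-t differential expression, core-gene
# intersection and the ddCt utility.

#' Empirical-Bayes location/scale batch adjustment
#'
#' Parametric empirical-Bayes batch correction for log-scale expression.
#' Each gene is standardized with a no-batch model; per-batch per-gene
#' location (normal prior) and scale (inverse-gamma prior) are estimated
#' with EB shrinkage across genes, removed, and the data back-transformed.
#'
#' @param x Genes x samples log2 matrix.
#' @param batch Character/factor vector of batch labels, one per sample (or
#'   an annotation data.frame with `sample_id` and `batch` columns).
#' @param mean_only If `TRUE`, adjust locations only (no scale adjustment).
#' @param shrink If `FALSE`, EB shrinkage is disabled and per-batch estimates
#'   are used directly (direct standardization).
#' @return The adjusted matrix, same dimensions and dimnames.
#' @export
combat_adjust <- function(x, batch, mean_only = FALSE, shrink = TRUE) {
  validate_expression(x)
  if (is.data.frame(batch)) {
    batch <- batch$batch[match(colnames(x), batch$sample_id)]
  }
  stopifnot(length(batch) == ncol(x))
  batch <- factor(batch)
  if (nlevels(batch) < 2) {
    message("single batch: nothing to adjust")
    return(x)
  }
  nb <- table(batch)
  if (any(nb < 2)) {
    stop("batch(es) with a single sample: ",
         paste(names(nb)[nb < 2], collapse = ", "))
  }
  n <- ncol(x)
  levs <- levels(batch)
  bidx <- lapply(levs, function(l) which(batch == l))
  ni <- lengths(bidx)

  batch_means <- vapply(bidx, function(j) rowMeans(x[, j, drop = FALSE]),
                        numeric(nrow(x)))
  alpha <- as.numeric(batch_means %*% (ni / n))     # grand (weighted) mean
  resid <- x - batch_means[, as.integer(batch)]
  sigma2 <- rowSums(resid^2) / n
  const <- sigma2 <= .Machine$double.eps
  if (any(const)) {
    message(sum(const), " zero-variance gene(s) passed through unadjusted")
  }
  sigma <- sqrt(pmax(sigma2, .Machine$double.eps))

  z <- (x - alpha) / sigma
  gamma_hat <- vapply(bidx, function(j) rowMeans(z[, j, drop = FALSE]),
                      numeric(nrow(x)))
  delta2_hat <- vapply(seq_along(bidx), function(i) {
    j <- bidx[[i]]
    rowSums((z[, j, drop = FALSE] - gamma_hat[, i])^2) / (ni[i] - 1)
  }, numeric(nrow(x)))

  gamma_star <- gamma_hat
  delta2_star <- delta2_hat
  if (shrink) {
    for (i in seq_along(bidx)) {
      gbar <- mean(gamma_hat[, i]); tau2 <- stats::var(gamma_hat[, i])
      m <- mean(delta2_hat[, i]); s2 <- stats::var(delta2_hat[, i])
      a <- (2 * s2 + m^2) / s2                      # inverse-gamma shape
      b <- (m * s2 + m^3) / s2                      # inverse-gamma scale
      g <- gamma_hat[, i]; d2 <- delta2_hat[, i]
      zi <- z[, bidx[[i]], drop = FALSE]
      for (it in 1:200) {
        g_new <- (ni[i] * tau2 * gamma_hat[, i] + d2 * gbar) /
          (ni[i] * tau2 + d2)
        ss <- rowSums((zi - g_new)^2)
        d2_new <- (b + ss / 2) / (ni[i] / 2 + a - 1)
        if (max(abs(g_new - g), abs(d2_new - d2)) < 1e-10) {
          g <- g_new; d2 <- d2_new; break
        }
        g <- g_new; d2 <- d2_new
      }
      gamma_star[, i] <- g
      delta2_star[, i] <- d2
    }
  }
  if (mean_only) delta2_star[] <- 1

  adj <- z
  for (i in seq_along(bidx)) {
    adj[, bidx[[i]]] <- (z[, bidx[[i]], drop = FALSE] - gamma_star[, i]) /
      sqrt(delta2_star[, i])
  }
  out <- adj * sigma + alpha
  out[const, ] <- x[const, ]
  attributes(out) <- attributes(x)
  out
}

#' Moderated two-group t-test with empirical-Bayes variance shrinkage
#'
#' Per-gene pooled-variance t-statistics with gene variances shrunk toward a
#' common prior. The prior degrees of freedom `d0` and prior variance `s0^2`
#' are fitted by method of moments on the log pooled variances (scaled
#' inverse chi-square model); the moderated t has `d_residual + d0` degrees
#' of freedom. P-values are BH-adjusted across genes.
#'
#' @param x Genes x samples log2 matrix.
#' @param group_a,group_b Disjoint character vectors of sample ids (each of
#'   size >= 2). log2FC is mean(group_b) - mean(group_a).
#' @param d0 Optional prior df override; `0` disables shrinkage and yields
#'   the ordinary pooled two-sample t.
#' @return A data.frame (one row per gene, input order): `gene`, `log2fc`,
#'   `t`, `p`, `p_adj`; attributes `d0` and `s0_sq`.
#' @export
moderated_ttest <- function(x, group_a, group_b, d0 = NULL) {
  validate_expression(x)
  if (length(intersect(group_a, group_b))) {
    stop("groups overlap: ",
         paste(utils::head(intersect(group_a, group_b)), collapse = ", "))
  }
  miss <- setdiff(c(group_a, group_b), colnames(x))
  if (length(miss)) stop("unknown sample id(s): ",
                         paste(utils::head(miss), collapse = ", "))
  na <- length(group_a); nb <- length(group_b)
  if (na < 2 || nb < 2) stop("each group needs >= 2 samples")

  xa <- x[, group_a, drop = FALSE]; xb <- x[, group_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  lfc <- mb - ma
  df_resid <- na + nb - 2
  ss <- rowSums((xa - ma)^2) + rowSums((xb - mb)^2)
  s2 <- ss / df_resid

  if (is.null(d0)) {
    fit <- fit_inv_chisq(s2, df_resid)
    d0 <- fit$d0; s0_sq <- fit$s0_sq
  } else if (d0 == 0) {
    s0_sq <- 0
  } else {
    pos <- s2 > 0
    s0_sq <- if (any(pos)) exp(mean(log(s2[pos]))) else 1
  }
  d0 <- min(d0, 1e6)

  s2_post <- if (d0 > 0) (d0 * s0_sq + df_resid * s2) / (d0 + df_resid) else s2
  se <- sqrt(s2_post * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, sign(lfc) * Inf))
  df_total <- df_resid + d0
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- data.frame(gene = rownames(x), log2fc = lfc, t = tstat, p = p,
                    p_adj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "d0") <- d0
  attr(res, "s0_sq") <- s0_sq
  res
}

# method-of-moments fit of a scaled inverse chi-square to gene variances,
# on the log scale (z = log s^2): E z and Var z involve di/trigamma terms.
fit_inv_chisq <- function(s2, df) {
  pos <- s2 > 0
  if (sum(pos) < 2) return(list(d0 = 1e6, s0_sq = max(mean(s2), 1e-12)))
  z <- log(s2[pos])
  e_z <- mean(z) - digamma(df / 2) + log(df / 2)
  excess <- stats::var(z) - trigamma(df / 2)
  if (is.na(excess) || excess <= 0) {
    return(list(d0 = 1e6, s0_sq = exp(e_z)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_sq <- exp(e_z + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = min(d0, 1e6), s0_sq = s0_sq)
}

# Newton solve of trigamma(y) = x for y > 0
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (-dif / y < 1e-10) break
  }
  y
}

#' Select differentially expressed genes at fixed thresholds
#'
#' Keeps genes with adjusted p strictly below `p_adj_max` and absolute
#' log2 fold change strictly above `abs_lfc_min` (a gene at exactly the
#' fold-change threshold is excluded). Order follows the input table.
#'
#' @param deg A table from [moderated_ttest()].
#' @param p_adj_max Adjusted-p cut (default 0.05).
#' @param abs_lfc_min Absolute log2FC cut (default 0.2).
#' @return Character vector of gene ids.
#' @export
select_degs <- function(deg, p_adj_max = 0.05, abs_lfc_min = 0.2) {
  stopifnot(p_adj_max > 0, p_adj_max <= 1, abs_lfc_min >= 0)
  if (!nrow(deg)) return(character(0))
  deg$gene[deg$p_adj < p_adj_max & abs(deg$log2fc) > abs_lfc_min]
}

#' Intersect DEGs with a depression-associated gene list
#'
#' @param degs Character vector of DEG ids (order preserved).
#' @param depression_genes Character vector of depression-associated genes.
#' @return The intersection, ordered as in `degs`. Empty intersections warn
#'   (downstream NMF subtyping will refuse an empty panel).
#' @export
intersect_core_genes <- function(degs, depression_genes) {
  core <- degs[degs %in% depression_genes]
  if (!length(core)) {
    warning("empty intersection between DEGs and the depression gene list")
  }
  core
}

#' Relative qPCR fold change by the 2^-ddCt method
#'
#' `ddCt = (ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl)`
#' and fold change `2^-ddCt`.
#'
#' @param ct_target_treat,ct_ref_treat Target/reference-gene Ct, treated.
#' @param ct_target_ctrl,ct_ref_ctrl Target/reference-gene Ct, control.
#' @return Fold change (vectorized).
#' @export
ddct_fold_change <- function(ct_target_treat, ct_ref_treat,
                             ct_target_ctrl, ct_ref_ctrl) {
  stopifnot(all(is.finite(c(ct_target_treat, ct_ref_treat,
                            ct_target_ctrl, ct_ref_ctrl))))
  ddct <- (ct_target_treat - ct_ref_treat) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
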