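make_subtyped <- function(n = 40, n_genes = 60, n_sig = 12, shift = 2,
                          seed = 1) {
  set.seed(seed)
  truth <- rep(c("D.cluster1", "D.cluster2"), each = n / 2)
  x <- matrix(rnorm(n_genes * n, 7, 1), n_genes, n,
              dimnames = list(sprintf("g%03d", 1:n_genes),
                              sprintf("s%03d", 1:n)))
  up <- 1:(n_sig / 2); dn <- (n_sig / 2 + 1):n_sig
  x[up, truth == "D.cluster2"] <- x[up, truth == "D.cluster2"] + shift
  x[dn, truth == "D.cluster2"] <- x[dn, truth == "D.cluster2"] - shift
  attr(x, "scale") <- "log2"
  names(truth) <- colnames(x)
  list(x = x, labels = truth, sig = rownames(x)[1:n_sig],
       panel = rownames(x)[up])
}

test_that("signature DEGs recover the planted contrast and stay null-calm", {
  d <- make_subtyped(n = 60, n_genes = 200, n_sig = 20, seed = 2)
  sig <- signature_degs(d$x, d$labels)
  expect_gte(mean(d$sig %in% sig), 0.9)
  # no planted difference: discoveries at the type-I level only
  null <- make_subtyped(n = 60, n_genes = 200, n_sig = 20, shift = 0,
                        seed = 3)
  expect_lte(length(signature_degs(null$x, null$labels)), 4)
  one <- d$labels; one[] <- "D.cluster1"
  expect_error(signature_degs(d$x, one), "both subtypes")
})

test_that("gene.cluster consensus agrees with planted structure", {
  d <- make_subtyped(n = 40, n_genes = 40, n_sig = 16, shift = 3, seed = 4)
  gc <- gene_cluster_consensus(d$x[d$sig, ], n_resample = 40, seed = 5,
                               inflammation_panel = d$panel, x = d$x)
  expect_gte(ari(gc, d$labels), 0.8)
  # orientation: the inflamed planted group is gene.cluster2
  expect_true(mean(gc[d$labels == "D.cluster2"] == "gene.cluster2") > 0.9)
  # duplicated sample is always co-assigned with its copy
  xdup <- cbind(d$x[d$sig, ], dup = d$x[d$sig, 1])
  colnames(xdup)[ncol(xdup)] <- "dup"
  gc2 <- gene_cluster_consensus(xdup, n_resample = 40, seed = 6)
  cons <- attr(gc2, "consensus")
  expect_equal(cons["dup", colnames(d$x)[1]], 1)
  expect_identical(gene_cluster_consensus(d$x[d$sig, ], n_resample = 20,
                                          seed = 7),
                   gene_cluster_consensus(d$x[d$sig, ], n_resample = 20,
                                          seed = 7))
  expect_error(gene_cluster_consensus(d$x[d$sig, ], k = 3), "k = 2")
})

test_that("the D.score is PC1 + PC2, oriented toward the inflamed cluster", {
  for (s in 1:20) {
    d <- make_subtyped(seed = s)
    sc <- compute_dscore(d$x[d$sig, ], d$labels)
    expect_equal(sc$dscore, sc$pc1 + sc$pc2)
    expect_gt(mean(sc$dscore[d$labels == "D.cluster2"]),
              mean(sc$dscore[d$labels == "D.cluster1"]))
    expect_true(all(attr(sc, "orientation") %in% c(-1, 1)))
  }
})

test_that("the D.score is invariant to gene and sample order", {
  d <- make_subtyped(seed = 30)
  sc <- compute_dscore(d$x[d$sig, ], d$labels)
  perm_g <- sample(d$sig)
  sc_g <- compute_dscore(d$x[perm_g, ], d$labels)
  expect_equal(sc_g$dscore, sc$dscore, tolerance = 1e-8)
  perm_s <- sample(colnames(d$x))
  sc_s <- compute_dscore(d$x[d$sig, perm_s], d$labels)
  expect_equal(sc_s$dscore[match(sc$sample_id, sc_s$sample_id)], sc$dscore,
               tolerance = 1e-8)
  # duplicated samples score identically
  xdup <- d$x[d$sig, ]; xdup <- cbind(xdup, dup = xdup[, 1])
  colnames(xdup)[ncol(xdup)] <- "dup"
  labs <- c(d$labels, dup = unname(d$labels[1]))
  sc_d <- compute_dscore(xdup, labs)
  expect_equal(sc_d$dscore[sc_d$sample_id == "dup"],
               sc_d$dscore[sc_d$sample_id == colnames(d$x)[1]])
  flat <- matrix(5, 10, 10, dimnames = list(paste0("g", 1:10),
                                            paste0("s", 1:10)))
  expect_error(compute_dscore(flat, d$labels), "constant")
})

test_that("median stratification uses a strict cut", {
  sc <- data.frame(sample_id = paste0("s", 1:4), pc1 = 0, pc2 = 0,
                   dscore = c(1, 2, 3, 4))
  st <- stratify(sc)
  expect_equal(st$stratum, c("low", "low", "high", "high"))
  sc3 <- sc[1:3, ]; sc3$dscore <- c(1, 2, 3)
  expect_equal(stratify(sc3)$stratum, c("low", "low", "high"))
  same <- sc; same$dscore <- rep(2, 4)
  expect_warning(st2 <- stratify(same), "low stratum")
  expect_true(all(st2$stratum == "low"))
  expect_equal(stratify(sc, rule = 3.5)$stratum,
               c("low", "low", "low", "high"))
})

test_that("response association matches the closed-form chi-square", {
  perfect <- matrix(c(20, 0, 0, 20), 2, 2, byrow = TRUE)
  res <- response_association(perfect)
  # n(ad - bc)^2 / (r1 r2 c1 c2) = 40 * 400^2 / 20^4 = 40
  expect_equal(res$statistic, 40)
  expect_true(res$haldane_corrected)
  expect_true(is.finite(res$odds_ratio))

  flat <- matrix(10, 2, 2)
  res2 <- response_association(flat)
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  expect_false(res2$haldane_corrected)

  strata <- rep(c("high", "low"), each = 10)
  resp <- rep(c("non-responder", "responder"), times = c(12, 8))
  res3 <- response_association(strata, resp)
  expect_equal(sum(res3$table), 20)
  degen <- response_association(rep("high", 10),
                                rep(c("responder", "non-responder"), 5))
  expect_true(is.na(degen$p_value))
})

test_that("marker panels are compared gene-wise with significance bins", {
  d <- make_subtyped(n = 40, n_genes = 30, n_sig = 10, shift = 0, seed = 8)
  groups <- d$labels
  mc <- marker_compare(d$x, groups, rownames(d$x)[1:5])
  expect_true(all(mc$results$signif == "ns"))

  d2 <- make_subtyped(n = 40, n_genes = 30, n_sig = 10, shift = 2, seed = 9)
  panel <- d2$panel                          # planted up in D.cluster2
  mc2 <- marker_compare(d2$x, d2$labels, c(panel, "ghost"))
  expect_equal(mc2$skipped, "ghost")
  expect_false("ghost" %in% mc2$results$gene)
  expect_true(all(mc2$results$signif == "****"))
  expect_true(all(mc2$results$direction == 1))
  mc3 <- marker_compare(d2$x, d2$labels, panel, test = "ttest")
  expect_true(all(mc3$results$p < 1e-4))
})
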