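test_that("single-batch input is returned unchanged", {
  x <- toy_expression(20, 8)
  expect_message(y <- combat_adjust(x, rep("b1", 8)), "nothing to adjust")
  expect_equal(y, x, tolerance = 1e-10)
})

test_that("a pure constant batch shift is removed exactly without shrinkage", {
  x <- toy_expression(30, 12, seed = 7)
  shift <- rnorm(30)
  x[, 7:12] <- x[, 7:12] + shift
  batch <- rep(c("a", "b"), each = 6)
  y <- combat_adjust(x, batch, mean_only = TRUE, shrink = FALSE)
  ma <- rowMeans(y[, 1:6]); mb <- rowMeans(y[, 7:12])
  expect_lt(max(abs(ma - mb)), 1e-8)
  # grand mean per gene is preserved exactly in this setting
  expect_lt(max(abs(rowMeans(y) - rowMeans(x))), 1e-8)
})

test_that("grand means are approximately preserved under EB defaults", {
  x <- toy_expression(200, 20, seed = 8)
  batch <- rep(c("a", "b"), each = 10)
  x[, batch == "b"] <- x[, batch == "b"] + rnorm(200, sd = 0.5)
  y <- combat_adjust(x, batch)
  expect_lt(max(abs(rowMeans(y) - rowMeans(x))), 0.2)
  expect_lt(mean(abs(rowMeans(y) - rowMeans(x))), 0.05)
})

test_that("degenerate batches are rejected and constant genes passed through", {
  x <- toy_expression(10, 5)
  expect_error(combat_adjust(x, c("a", "a", "a", "a", "b")), "single sample")
  x2 <- toy_expression(10, 8)
  x2[3, ] <- 5
  expect_message(y <- combat_adjust(x2, rep(c("a", "b"), each = 4)),
                 "zero-variance")
  expect_equal(unname(y[3, ]), rep(5, 8))
})

test_that("batch adjustment matches the reference EB implementation", {
  skip_if_not_installed("sva")
  set.seed(11)
  x <- toy_expression(300, 30, seed = 11)
  batch <- rep(c("a", "b", "c"), each = 10)
  for (b in unique(batch)) {
    x[, batch == b] <- x[, batch == b] + rnorm(300, sd = 0.4)
  }
  ours <- combat_adjust(x, batch)
  ref <- suppressMessages(sva::ComBat(dat = unclass(x)[, ], batch = batch))
  expect_lt(max(abs(ours - ref)), 1e-3)
})

test_that("batch-confounded null data is calibrated after adjustment", {
  rates <- vapply(1:5, function(s) {
    x <- toy_expression(500, 20, seed = 100 + s)
    batch <- rep(c("a", "b"), each = 10)
    x[, batch == "b"] <- x[, batch == "b"] + rnorm(500, sd = 1)
    y <- combat_adjust(x, batch)
    deg <- moderated_ttest(y, colnames(x)[1:10], colnames(x)[11:20])
    mean(deg$p < 0.05)
  }, 0)
  expect_lte(mean(rates), 0.07)
})

test_that("identical groups give zero fold change and p = 1", {
  x <- toy_expression(10, 8)
  x[1, ] <- rep(c(1, 2, 3, 4), 2)
  deg <- moderated_ttest(x, colnames(x)[1:4], colnames(x)[5:8])
  expect_equal(deg$log2fc[1], 0)
  expect_equal(deg$p[1], 1)
})

test_that("disabling shrinkage recovers the textbook pooled t", {
  x <- toy_expression(50, 12, seed = 21)
  ga <- colnames(x)[1:6]; gb <- colnames(x)[7:12]
  deg <- moderated_ttest(x, ga, gb, d0 = 0)
  # independent pooled two-sample t computed from first principles
  for (g in c(1, 17, 50)) {
    a <- x[g, ga]; b <- x[g, gb]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 10
    t_ref <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / 6 + 1 / 6))
    p_ref <- 2 * pt(-abs(t_ref), df = 10)
    expect_equal(deg$t[g], t_ref, tolerance = 1e-10)
    expect_equal(deg$p[g], p_ref, tolerance = 1e-10)
  }
  expect_error(moderated_ttest(x, ga, c(ga[1], gb)), "overlap")
})

test_that("BH adjustment matches the hand step-up computation", {
  x <- toy_expression(40, 10, seed = 31)
  deg <- moderated_ttest(x, colnames(x)[1:5], colnames(x)[6:10])
  p <- deg$p
  m <- length(p)
  o <- order(p)
  hand <- numeric(m)
  hand[o] <- rev(cummin(rev(p[o] * m / seq_len(m))))
  expect_equal(deg$p_adj, pmin(hand, 1), tolerance = 1e-12)
  # frozen hand case: p = (.01,.02,.03,.04), m = 4 -> all adjusted to .04
  hand4 <- rev(cummin(rev(c(.01, .02, .03, .04) * 4 / 1:4)))
  expect_equal(hand4, rep(0.04, 4))
})

test_that("moderated t agrees with the limma oracle", {
  skip_if_not_installed("limma")
  # homogeneous gene variances: both fits should drive the prior df very
  # large and the t statistics into near-perfect agreement
  pl <- planted_two_group(n_genes = 300, seed = 41)
  deg <- moderated_ttest(pl$x, pl$group1, pl$group2)
  design <- cbind(1, rep(c(0, 1), each = 10))
  fit <- limma::eBayes(limma::lmFit(unclass(pl$x)[, ], design))
  expect_equal(deg$log2fc, unname(fit$coefficients[, 2]), tolerance = 1e-10)
  expect_gt(cor(deg$t, fit$t[, 2]), 0.999)
  if (is.infinite(fit$df.prior)) {
    expect_gte(attr(deg, "d0"), 1e5)
  }
  # heterogeneous variances: a finite prior df, comparable between fits
  set.seed(42)
  x2 <- pl$x * exp(rnorm(300, sd = 0.8))
  deg2 <- moderated_ttest(x2, pl$group1, pl$group2)
  fit2 <- limma::eBayes(limma::lmFit(unclass(x2)[, ], design))
  expect_lt(abs(attr(deg2, "d0") - fit2$df.prior) / fit2$df.prior, 0.2)
  expect_gt(cor(deg2$t, fit2$t[, 2]), 0.999)
})

test_that("DEG selection applies strict cuts in table order", {
  tab <- data.frame(gene = paste0("g", 1:5),
                    log2fc = c(0.5, 0.2, -0.5, 0.21, 0.05),
                    t = 0, p = 0,
                    p_adj = c(0.01, 0.01, 0.04, 0.05, 0.001))
  # by hand: g1 (0.01,|0.5|) and g3 (0.04,|0.5|) pass; g2 fails |lfc| = 0.2
  # exactly; g4 fails p_adj = 0.05 exactly; g5 fails |lfc|
  expect_equal(select_degs(tab), c("g1", "g3"))
  expect_equal(select_degs(tab[0, ]), character(0))
})

test_that("core-gene intersection preserves DEG order", {
  expect_equal(intersect_core_genes(c("g1", "g2", "g3"), c("g2", "g3", "g4")),
               c("g2", "g3"))
  expect_warning(out <- intersect_core_genes("g1", "g9"), "empty")
  expect_length(out, 0)
})

test_that("ddCt fold changes match the closed form", {
  expect_equal(ddct_fold_change(20, 15, 22, 17), 1)
  expect_equal(ddct_fold_change(20, 16, 21, 16), 2)   # ddCt = -1
  expect_equal(ddct_fold_change(24, 18, 26, 18), 4)   # ddCt = -2 by hand
  expect_error(ddct_fold_change(NA, 1, 1, 1), "finite")
})
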