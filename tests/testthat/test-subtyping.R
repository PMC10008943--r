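test_that("nonnegativity mapping behaves per mode", {
  x <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(c("a", "b"), c("s", "t")))
  expect_equal(to_nonnegative(x, "offset"), x)
  xm <- x; xm[1, 1] <- -3
  expect_equal(min(to_nonnegative(xm, "offset")), 0)
  pn <- to_nonnegative(xm, "posneg")
  expect_equal(dim(pn), c(4, 2))
  expect_true(all(pn[1:2, ] * pn[3:4, ] == 0))
  expect_error(to_nonnegative(xm, "none"), "negative")
  expect_equal(to_nonnegative(x, "none"), x)
})

test_that("exactly factorizable rank-1 input reaches near-zero divergence", {
  set.seed(5)
  w <- runif(12, 0.5, 2); h <- runif(9, 0.5, 2)
  a <- outer(w, h)
  dimnames(a) <- list(paste0("g", 1:12), paste0("s", 1:9))
  fit <- nmf_factorize(a, k = 1, seed = 3)
  expect_lt(tail(fit$trace, 1), 1e-8)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  expect_equal(unname(colSums(fit$W)), 1)    # scale fixed in W
})

test_that("KL divergence is non-increasing for random instances", {
  set.seed(6)
  for (i in 1:20) {
    a <- matrix(rexp(15 * 8), 15, 8,
                dimnames = list(paste0("g", 1:15), paste0("s", 1:8)))
    fit <- nmf_factorize(a, k = sample(2:4, 1), seed = i, max_iter = 300)
    expect_true(all(diff(fit$trace) <= 1e-8 * pmax(1, abs(fit$trace[-1]))))
  }
})

test_that("invalid NMF inputs are rejected", {
  a <- matrix(1, 4, 4, dimnames = list(paste0("g", 1:4), paste0("s", 1:4)))
  bad <- a; bad[2, 2] <- -0.5
  expect_error(nmf_factorize(bad, 2), "negative")
  zr <- a; zr[3, ] <- 0
  expect_error(nmf_factorize(zr, 2), "row")
  zc <- a; zc[, 2] <- 0
  expect_error(nmf_factorize(zc, 2), "column")
  expect_error(nmf_factorize(a, 4), "k must")
})

test_that("consensus diagnostics match their closed forms", {
  # perfect binary block consensus: dispersion = 1, cophenetic = 1
  cb <- kronecker(diag(2), matrix(1, 4, 4))
  dimnames(cb) <- list(paste0("s", 1:8), paste0("s", 1:8))
  m <- ibddep:::consensus_metrics(cb, 2)
  expect_equal(m$dispersion, 1)
  expect_equal(m$cophenetic, 1)
  # maximally ambiguous: all off-diagonal 0.5 -> dispersion 0
  ca <- matrix(0.5, 8, 8, dimnames = dimnames(cb)); diag(ca) <- 1
  expect_equal(ibddep:::consensus_metrics(ca, 2)$dispersion, 0)
})

test_that("planted blocks give a crisp consensus and faithful labels", {
  set.seed(8)
  n <- 30
  truth <- rep(1:2, each = n / 2)
  a <- matrix(rnorm(20 * n, 7, 0.2), 20, n)
  a[1:10, truth == 2] <- a[1:10, truth == 2] + 2
  a[11:20, truth == 2] <- a[11:20, truth == 2] - 2
  dimnames(a) <- list(paste0("g", 1:20), paste0("s", 1:n))
  cr <- consensus_cluster(to_nonnegative(a), 2, n_runs = 40, seed = 9,
                          max_iter = 500)
  cmat <- cr$consensus
  within <- cmat[truth == 1, truth == 1][upper.tri(diag(n / 2))]
  between <- cmat[truth == 1, truth == 2]
  expect_true(all(within > 0.95) &&
              all(cmat[truth == 2, truth == 2][upper.tri(diag(n / 2))] > 0.95))
  # an occasional degenerate restart may contribute one co-assignment
  expect_lte(max(between), 0.05)
  expect_gt(cr$cophenetic, 0.99)
  expect_equal(ari(cr$labels, truth), 1)
  # consensus matrix invariants
  expect_true(isSymmetric(cmat, tol = 1e-12))
  expect_true(all(diag(cmat) == 1))
  expect_true(all(cmat >= 0 & cmat <= 1))
  # label equivariance: permuting samples permutes the partition
  perm <- sample(n)
  cr2 <- consensus_cluster(to_nonnegative(a[, perm]), 2, n_runs = 40,
                           seed = 9, max_iter = 500)
  expect_equal(ari(cr2$labels, truth[perm]), 1)
})

test_that("rank selection recovers a planted k = 2 and flags pure noise", {
  set.seed(10)
  n <- 24
  truth <- rep(1:2, each = n / 2)
  a <- matrix(rnorm(16 * n, 7, 0.3), 16, n)
  a[1:8, truth == 2] <- a[1:8, truth == 2] + 3
  a[9:16, truth == 2] <- a[9:16, truth == 2] - 3
  dimnames(a) <- list(paste0("g", 1:16), paste0("s", 1:n))
  sel <- select_rank(to_nonnegative(a), k_range = 2:4, n_runs = 20,
                     seed = 11, max_iter = 400)
  expect_equal(sel$k, 2)
  expect_equal(nrow(sel$diagnostics), 3)
  expect_false(sel$low_confidence)

  sel2 <- select_rank(to_nonnegative(a), k_range = 2, n_runs = 10, seed = 12,
                      max_iter = 400)
  expect_equal(sel2$k, 2)
  expect_equal(nrow(sel2$diagnostics), 1)

  # pure noise: no crash, diagnostics for every k, flag consistent with
  # the best cophenetic coefficient
  noise <- matrix(rexp(16 * n), 16, n, dimnames = dimnames(a))
  for (s in 1:3) {
    seln <- select_rank(noise, k_range = 2:3, n_runs = 8, seed = s,
                        max_iter = 300)
    expect_equal(nrow(seln$diagnostics), 2)
    expect_true(all(is.finite(seln$diagnostics$cophenetic)))
    expect_identical(seln$low_confidence,
                     max(seln$diagnostics$cophenetic) < 0.9)
  }
})

test_that("subtype orientation follows the inflammation panel", {
  set.seed(13)
  n <- 20
  truth <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(10 * n, 7, 0.2), 10, n,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:n)))
  panel <- paste0("g", 1:5)
  x[1:5, truth == 2] <- x[1:5, truth == 2] + 3   # panel up in subtype 2
  cr <- consensus_cluster(to_nonnegative(x), 2, n_runs = 10, seed = 14,
                          max_iter = 400)
  labs <- assign_subtypes(cr, x, panel)
  expect_true(all(labs[truth == 2] == "D.cluster2"))
  expect_true(all(labs[truth == 1] == "D.cluster1"))
  # swapping the arbitrary cluster indices leaves the final labels unchanged
  cr_sw <- cr; cr_sw$labels <- 3L - cr$labels
  expect_identical(assign_subtypes(cr_sw, x, panel), labs)
  expect_error(assign_subtypes(cr, x, character(0)), "empty")
  cr3 <- cr; cr3$k <- 3
  expect_error(assign_subtypes(cr3, x, panel), "k = 2")
})
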