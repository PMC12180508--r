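test_that("a noiseless planted 2-block partition is recovered exactly", {
  lab <- rep(1:2, each = 12)
  m <- planted_matrix(lab)
  fit <- wsbm_fit(m, 2, n_restarts = 3, seed = 1)
  expect_equal(mclust::adjustedRandIndex(fit$labels, lab), 1)
  expect_equal(sort(unique(c(fit$mu))), c(-0.6, 0.6))
})

test_that("K = 1 reduces to the off-diagonal mean and variance", {
  set.seed(10)
  m <- matrix(rnorm(100), 10); m <- (m + t(m)) / 2; diag(m) <- NA
  colnames(m) <- rownames(m) <- paste0("v", 1:10)
  fit <- wsbm_fit(m, 1)
  x <- m[lower.tri(m)]
  expect_equal(fit$mu[1, 1], mean(x))
  expect_equal(fit$sigma2, mean((x - mean(x))^2))
  expect_equal(fit$K, 1)
})

test_that("relabeled initializations reach the same lower bound", {
  set.seed(20)
  lab <- rep(1:3, each = 8)
  m <- planted_matrix(lab, hi = 0.5, lo = -0.2, sd = 0.15)
  f1 <- wsbm_fit(m, 3, n_restarts = 1, seed = 5)
  f2 <- wsbm_fit(m, 3, n_restarts = 1, seed = 6)
  expect_equal(f1$elbo, f2$elbo, tolerance = 1e-6)
  expect_equal(mclust::adjustedRandIndex(f1$labels, f2$labels), 1)
})

test_that("the evidence lower bound never decreases within a run", {
  for (s in 1:6) {
    set.seed(s)
    lab <- sample(1:3, 20, replace = TRUE)
    m <- planted_matrix(pmax(lab, 1), hi = 0.4, lo = -0.3, sd = 0.5)
    fit <- wsbm_fit(m, 3, n_restarts = 2, seed = s)
    tr <- fit$elbo_trace
    if (length(tr) > 1) {
      expect_true(all(diff(tr) >= -1e-8 * (abs(tr[-length(tr)]) + 1)))
    }
  }
})

test_that("block means match hand enumeration on the 4-node toy", {
  m <- matrix(0.2, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.6
  m[3, 4] <- m[4, 3] <- 0.3
  diag(m) <- NA
  colnames(m) <- rownames(m) <- paste0("v", 1:4)
  bm <- block_means(m, c(1, 1, 2, 2))
  expect_equal(bm[1, 1], 0.6)
  expect_equal(bm[2, 2], 0.3)
  expect_equal(bm[1, 2], 0.2)
  expect_equal(bm[2, 1], 0.2)
})

test_that("block means on an all-equal matrix are that constant, and respect relabeling", {
  m <- matrix(0.37, 6, 6); diag(m) <- NA
  colnames(m) <- rownames(m) <- paste0("v", 1:6)
  lab <- c(1, 1, 2, 2, 3, 3)
  bm <- block_means(m, lab)
  expect_true(all(bm == 0.37))
  # consistent relabeling permutes rows/cols of the block-mean matrix
  set.seed(30)
  m2 <- matrix(rnorm(36), 6); m2 <- m2 + t(m2); diag(m2) <- NA
  colnames(m2) <- rownames(m2) <- paste0("v", 1:6)
  perm <- c(3, 1, 2)
  bm1 <- block_means(m2, lab)
  bm2 <- block_means(m2, perm[lab])
  expect_equal(bm2[perm, perm], bm1)
})

test_that("a single-member cluster's within-block mean is missing", {
  m <- matrix(0.2, 4, 4); diag(m) <- NA
  colnames(m) <- rownames(m) <- paste0("v", 1:4)
  bm <- block_means(m, c(1, 2, 2, 2))
  expect_true(is.na(bm[1, 1]))
  expect_false(anyNA(bm[1, 2]))
})

test_that("ICL prefers one cluster for homogeneous noise and the planted K otherwise", {
  ok_null <- 0
  for (s in 1:5) {
    set.seed(400 + s)
    m <- matrix(rnorm(30 * 30, 0, 0.3), 30); m <- (m + t(m)) / 2; diag(m) <- NA
    colnames(m) <- rownames(m) <- paste0("v", 1:30)
    sel <- select_k(m, k_range = 1:3, n_restarts = 4, seed = s)
    if (sel$K == 1) ok_null <- ok_null + 1
    expect_equal(nrow(sel$icl_table), 3)
  }
  expect_gte(ok_null, 4)

  set.seed(88)
  lab <- rep(1:3, each = 10)
  m <- planted_matrix(lab, hi = 0.6, lo = -0.2, sd = 0.15)
  sel <- select_k(m, k_range = 1:5, n_restarts = 4, seed = 2)
  expect_equal(sel$K, 3)
  expect_equal(mclust::adjustedRandIndex(sel$labels, lab), 1)
})

test_that("fitted block means equal brute-force per-block sample means", {
  set.seed(55)
  lab <- rep(1:3, each = 8)
  m <- planted_matrix(lab, hi = 0.5, lo = -0.3, sd = 0.3)
  fit <- wsbm_fit(m, 3, n_restarts = 3, seed = 7)
  for (r in 1:fit$K) for (s in r:fit$K) {
    sel_r <- fit$labels == r; sel_s <- fit$labels == s
    block <- m[sel_r, sel_s, drop = FALSE]
    vals <- if (r == s) block[lower.tri(block)] else c(block)
    vals <- vals[!is.na(vals)]
    expect_equal(fit$mu[r, s], mean(vals))
  }
})

test_that("per-group WSBM on identical matrices yields identical partitions", {
  set.seed(66)
  lab <- rep(1:2, each = 10)
  m <- planted_matrix(lab, hi = 0.5, lo = -0.4, sd = 0.2)
  f1 <- per_group_wsbm(m, k_range = 1:3, n_restarts = 3, seed = 3)
  f2 <- per_group_wsbm(m, k_range = 1:3, n_restarts = 3, seed = 3)
  cmp <- compare_partitions(f1$labels, f2$labels)
  expect_equal(cmp$ari, 1)
  expect_equal(unname(rowSums(cmp$crosstab)),
               unname(as.integer(table(f1$labels))))
})

test_that("requesting more clusters than nodes fails, as does an empty range", {
  m <- planted_matrix(rep(1:2, each = 3))
  expect_error(wsbm_fit(m, 7), "exceed")
  expect_error(select_k(m, k_range = integer(0)), "empty")
})

test_that("the block permutation test covers all unique blocks of a fixed partition", {
  spec <- preset_planted_delta(effect = 0.6, seed = 41,
                               sizes = c(case_a = 80, case_b = 80,
                                         control_a = 60, control_b = 60))
  sp <- std_pair(generate_cohort(spec))
  plan <- permutation_plan(n_perm = 100, seed = 11)
  bt <- block_permutation_test(sp$scores, sp$labels, spec$clusters, plan)
  K <- max(spec$clusters)
  expect_equal(nrow(bt), K * (K + 1) / 2)
  expect_equal(attr(bt, "threshold"), 0.05 / (K * (K + 1) / 2))
  planted <- bt[bt$r == 1 & bt$s == 2, ]
  expect_lt(planted$p, 0.05)
  expect_equal(planted$direction, 1)
  # graphml export round-trips through igraph
  f <- withr::local_tempfile(fileext = ".graphml")
  g <- export_block_graphml(bt, f)
  expect_true(file.exists(f))
  expect_equal(igraph::vcount(g), K)
})
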