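test_that("nodal degree is the off-diagonal row mean of Fisher-Z values", {
  r <- matrix(0.5, 4, 4); diag(r) <- 1
  dimnames(r) <- list(paste0("s", 1:4), paste0("s", 1:4))
  net <- structure(list(r = r, n_pairs = matrix(99, 4, 4),
                        scale_ids = paste0("s", 1:4), group = "g"),
                   class = "corr_network")
  deg <- nodal_degree(fisher_z(net))
  expect_equal(unname(deg), rep(atanh(0.5), 4))

  z0 <- as_z_network(matrix(0, 3, 3))
  expect_equal(unname(nodal_degree(z0)), rep(0, 3))

  z <- matrix(c(NA, 0.2, 0.6, 0.2, NA, 0, 0.6, 0, NA), 3)
  expect_equal(unname(nodal_degree(z))[1], 0.4)
})

test_that("degree congruence hits +-1 in the exact cases and checks variance", {
  d <- c(0.1, 0.4, 0.2, 0.5)
  expect_equal(degree_congruence(d, d), 1)
  expect_equal(degree_congruence(d, -d + 0.7), -1)
  expect_error(degree_congruence(d, rep(1, 4)), "variance")
  expect_error(degree_congruence(d, d[1:3]), "length")
})

test_that("degree congruence is high when two groups share the population network", {
  spec <- preset_null(p = 20, sizes = c(case_a = 400, case_b = 400,
                                        control_a = 200, control_b = 200),
                      seed = 2)
  sp <- std_pair(generate_cohort(spec))
  obs_a <- fisher_z(correlation_network(sp$std_a))
  obs_b <- fisher_z(correlation_network(sp$std_b))
  expect_gt(degree_congruence(nodal_degree(obs_a), nodal_degree(obs_b)), 0.8)
})

test_that("Deming regression is exact on a perfect line", {
  x <- seq(0, 5, by = 0.5)
  fit <- deming_fit(x, 2 * x + 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$se_slope, 0)
  expect_equal(fit$se_intercept, 0)
  expect_equal(fit$p_slope_vs_1, 0)       # exact fit, slope != 1
  expect_equal(deming_fit(x, x)$p_slope_vs_1, 1)   # exactly the identity line
})

test_that("swapping x and y inverts the Deming slope at lambda = 1", {
  set.seed(8)
  x <- rnorm(40); y <- 0.7 * x + rnorm(40, 0, 0.4)
  f1 <- deming_fit(x, y); f2 <- deming_fit(y, x)
  expect_equal(f2$slope, 1 / f1$slope, tolerance = 1e-10)
  expect_equal(f2$intercept, -f1$intercept / f1$slope, tolerance = 1e-10)
})

test_that("the Deming fit minimizes orthogonal squared distance over a local grid", {
  set.seed(15)
  x <- rnorm(20); y <- 1.3 * x + 0.2 + rnorm(20, 0, 0.5)
  fit <- deming_fit(x, y)
  ssq <- function(b, a) sum((y - a - b * x)^2) / (1 + b^2)
  best <- ssq(fit$slope, fit$intercept)
  for (db in seq(-0.1, 0.1, by = 0.02)) {
    for (da in seq(-0.1, 0.1, by = 0.02)) {
      expect_gte(ssq(fit$slope + db, fit$intercept + da), best - 1e-12)
    }
  }
})

test_that("jackknife CIs cover a planted unit slope in at least 90% of replicates", {
  hits <- vapply(seq_len(200), function(i) {
    set.seed(3000 + i)
    t_true <- rnorm(53, 0, 0.5)
    x <- t_true + rnorm(53, 0, 0.15)
    y <- t_true + rnorm(53, 0, 0.15)
    fit <- deming_fit(x, y)
    tcrit <- qt(0.975, df = 51)
    abs(fit$slope - 1) <= tcrit * fit$se_slope
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fingerprint divergence is 0 for identical rows, 2 for negated rows", {
  set.seed(23)
  m <- matrix(rnorm(3000), 500, 6, dimnames = list(NULL, paste0("s", 1:6)))
  z <- fisher_z(correlation_network(m, min_n = 10))
  fp0 <- fingerprint_divergence(z, z)
  expect_equal(fp0$divergence, rep(0, 6))
  zneg <- as_z_network(-z$z)
  fp2 <- fingerprint_divergence(z, zneg)
  expect_equal(fp2$divergence, rep(2, 6))
})

test_that("fingerprint divergence matches brute-force row correlations on a toy", {
  set.seed(44)
  za <- matrix(rnorm(16), 4); za <- za + t(za); diag(za) <- NA
  zb <- matrix(rnorm(16), 4); zb <- zb + t(zb); diag(zb) <- NA
  colnames(za) <- rownames(za) <- colnames(zb) <- rownames(zb) <- paste0("s", 1:4)
  fp <- fingerprint_divergence(za, zb)
  for (i in 1:4) {
    expect_equal(fp$divergence[i], 1 - cor(za[i, -i], zb[i, -i]))
  }
})

test_that("fingerprint divergence is invariant to a common positive affine transform", {
  set.seed(52)
  m <- matrix(rnorm(1200), 200, 6, dimnames = list(NULL, paste0("s", 1:6)))
  m2 <- matrix(rnorm(1200), 200, 6, dimnames = list(NULL, paste0("s", 1:6)))
  za <- fisher_z(correlation_network(m, min_n = 10))$z
  zb <- fisher_z(correlation_network(m2, min_n = 10))$z
  fp1 <- fingerprint_divergence(za, zb)
  fp2 <- fingerprint_divergence(2.5 * za + 0.3, 2.5 * zb + 0.3)
  expect_equal(fp1$divergence, fp2$divergence, tolerance = 1e-12)
})

test_that("degree equals the mean of each row's entries in the edge vector", {
  set.seed(61)
  m <- matrix(rnorm(1000), 100, 10, dimnames = list(NULL, paste0("s", 1:10)))
  z <- fisher_z(correlation_network(m, min_n = 10))
  deg <- nodal_degree(z)
  edges <- upper_triangle(z)
  for (sc in z$scale_ids) {
    vals <- edges$value[edges$scale_i == sc | edges$scale_j == sc]
    expect_equal(unname(deg[sc]), mean(vals))
  }
})

test_that("a planted degree boost is the top-ranked degree difference", {
  # scale 20's couplings strengthened in group A only (rewired home cluster
  # with high loading raises its coupling everywhere in A)
  spec <- preset_null(p = 12, sizes = c(case_a = 300, case_b = 300,
                                        control_a = 150, control_b = 150),
                      seed = 17)
  phi_hot <- spec$phi_a
  phi_hot[] <- 0.7; diag(phi_hot) <- 1
  spec$phi_a <- phi_hot   # group A globally more coherent
  sp <- std_pair(generate_cohort(spec))
  plan <- permutation_plan(n_perm = 200, seed = 3)
  res <- degree_difference_test(sp$scores, sp$labels, plan)
  expect_true(all(res$delta > 0))
  expect_lt(min(res$p), 0.05)
  expect_equal(attr(res, "threshold"), 0.05 / 12)
})

test_that("edgewise follow-up has p-1 partner rows and near-1 p for identical groups", {
  spec <- preset_null(p = 6, sizes = c(case_a = 30, case_b = 30,
                                       control_a = 30, control_b = 30), seed = 6)
  sp <- std_pair(generate_cohort(spec))
  # make group B's rows literally identical to group A's
  scores <- rbind(sp$std_a$values, sp$std_a$values)
  labels <- c(rep("case_a", nrow(sp$std_a$values)),
              rep("case_b", nrow(sp$std_a$values)))
  plan <- permutation_plan(n_perm = 30, seed = 12)
  ew <- edgewise_for_scale("s01_iI1", scores, labels, plan)
  expect_equal(nrow(ew), 5)
  expect_equal(ew$delta, rep(0, 5))
  expect_equal(ew$p, rep(1, 5))
  expect_s3_class(attr(ew, "deming"), "deming_fit")
  expect_error(edgewise_for_scale("nope", scores, labels, plan), "nope")
})

test_that("divergence-vs-effect-size correlation is exact on constructed data", {
  fp <- data.frame(scale_id = paste0("s", 1:6),
                   divergence = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6))
  es <- data.frame(scale_id = paste0("s", 1:6),
                   effect_a = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6) * 2,
                   effect_b = 0)
  out <- divergence_effectsize_corr(fp, es)
  expect_equal(out$r, 1)
  expect_error(divergence_effectsize_corr(fp, es[1:4, ]), "length")
})
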