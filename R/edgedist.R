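#' Pearson (non-excess) kurtosis
#'
#' b2 = m4 / m2^2 with moments about the sample mean and 1/n normalization.
#' On this scale a normal distribution has kurtosis 3; values above 3 are
#' leptokurtic (heavier tails).
#'
#' @param x Numeric vector, n >= 4, non-constant.
#' @return Scalar kurtosis.
#' @export
kurtosis_b2 <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("need at least 4 values")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("zero variance")
  mean((x - mean(x))^4) / m2^2
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' D = sup over x of |ECDF_a(x) - ECDF_b(x)|, the maximum vertical distance
#' between the two empirical cumulative distribution functions.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return Scalar D in \[0, 1\].
#' @export
ks_distance <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) stop("empty input")
  unname(suppressWarnings(stats::ks.test(a, b)$statistic))
}

# Exact permutation p for the two-sample KS distance on tiny inputs:
# enumerates all assignments of the pooled values into groups of the observed
# sizes. Used for property checks; not intended for large samples.
ks_exact_perm_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool)
  na <- length(a)
  obs <- ks_distance(a, b)
  combos <- utils::combn(n, na)
  d_null <- apply(combos, 2, function(ix) ks_distance(pool[ix], pool[-ix]))
  mean(d_null >= obs)
}

#' Compare the full edge-weight distributions between groups
#'
#' Treats each group's p(p-1)/2 unique Fisher-Z edges as a distribution and
#' compares the two groups three ways: absolute difference of means
#' (permutation p), the KS distance D (permutation p, with the asymptotic
#' ks.test p logged alongside), and each group's Pearson kurtosis
#' (descriptive; no significance test).
#'
#' @inheritParams degree_difference_test
#' @return One-row data frame: `mean_a`, `mean_b`, `abs_delta_mean`, `p_mean`,
#'   `ks_d`, `p_ks`, `p_ks_asymptotic`, `kurtosis_a`, `kurtosis_b`.
#' @export
edge_distribution_test <- function(scores, labels, plan, min_n = 10,
                                   null = NULL) {
  obs <- observed_z_pair(scores, labels, min_n)
  ea <- obs$a$z[lower.tri(obs$a$z)]
  eb <- obs$b$z[lower.tri(obs$b$z)]
  mean_a <- mean(ea); mean_b <- mean(eb)
  d_obs <- ks_distance(ea, eb)
  if (is.null(null)) {
    null <- null_distribution(scores, labels, plan,
                              statistics = list(mean_edge_diff = stat_mean_edge_diff,
                                                ks_d = stat_ks_d),
                              min_n = min_n)
  }
  p_mean <- empirical_p(abs(mean_a - mean_b), null$values$mean_edge_diff)
  p_ks <- empirical_p(d_obs, null$values$ks_d)
  p_asym <- suppressWarnings(stats::ks.test(ea, eb)$p.value)
  data.frame(
    mean_a = mean_a, mean_b = mean_b,
    abs_delta_mean = abs(mean_a - mean_b), p_mean = p_mean,
    ks_d = d_obs, p_ks = p_ks, p_ks_asymptotic = p_asym,
    kurtosis_a = kurtosis_b2(ea), kurtosis_b = kurtosis_b2(eb)
  )
}

#' Mean edge-weight difference test
#'
#' The absolute difference between the two groups' mean Fisher-Z edge values,
#' with an empirical p-value from group-label permutation.
#'
#' @inheritParams degree_difference_test
#' @return List with `mean_a`, `mean_b`, `abs_delta`, `p`.
#' @export
mean_edge_diff_test <- function(scores, labels, plan, min_n = 10, null = NULL) {
  res <- edge_distribution_test(scores, labels, plan, min_n = min_n, null = null)
  list(mean_a = res$mean_a, mean_b = res$mean_b,
       abs_delta = res$abs_delta_mean, p = res$p_mean)
}
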