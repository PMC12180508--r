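#' Nodal degree (global coupling score)
#'
#' Mean Fisher-Z-transformed correlation between one scale and all others:
#' the row mean of the Z-matrix over its p - 1 off-diagonal entries (the
#' masked diagonal is excluded; atanh(1) is infinite).
#'
#' @param z A `z_network` or a p x p Z-matrix with `NA` diagonal.
#' @return Named numeric vector of length p.
#' @export
nodal_degree <- function(z) {
  if (inherits(z, "z_network")) z <- z$z
  off <- z
  diag(off) <- NA_real_
  if (any(!is.finite(off[row(off) != col(off)]))) {
    stop("non-finite off-diagonal Fisher-Z value")
  }
  rowMeans(off, na.rm = TRUE)
}

#' Congruence of nodal degree between groups
#'
#' Pearson correlation across scales between the two groups' degree vectors:
#' the overall similarity of each scale's global coupling in the two groups.
#'
#' @param deg_a,deg_b Degree vectors over the same scale set.
#' @return Scalar correlation.
#' @export
degree_congruence <- function(deg_a, deg_b) {
  if (length(deg_a) != length(deg_b)) stop("degree vectors differ in length")
  if (stats::sd(deg_a) == 0 || stats::sd(deg_b) == 0) {
    stop("zero variance in a degree vector")
  }
  stats::cor(deg_a, deg_b)
}

#' Deming (errors-in-both-variables) regression
#'
#' Orthogonal least squares fit of y on x when both carry error, with error
#' variance ratio `lambda` (lambda = 1, the default, is orthogonal
#' regression: the fit line is the same whichever group is treated as x).
#' Slope is the closed form
#' \deqn{\hat\beta = \frac{s_{yy} - \lambda s_{xx} +
#'   \sqrt{(s_{yy}-\lambda s_{xx})^2 + 4\lambda s_{xy}^2}}{2 s_{xy}},}
#' intercept \eqn{\bar y - \hat\beta \bar x}. Standard errors are
#' leave-one-out jackknife; two-sided t-tests (n - 2 df) compare the slope
#' against 1 and the intercept against 0, i.e. against the identity line.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @param lambda Ratio of error variances var(err_y)/var(err_x), default 1.
#' @return Object of class `deming_fit`: slope, intercept, their jackknife
#'   SEs, p-values versus the identity line, `lambda`, `n`, and residuals
#'   (orthogonal signed distances).
#' @export
deming_fit <- function(x, y, lambda = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  est <- function(x, y) {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    if (sxy == 0) {
      if (abs(syy - lambda * sxx) < .Machine$double.eps * (syy + lambda * sxx)) {
        stop("degenerate configuration: s_xy = 0 and s_yy = lambda * s_xx")
      }
      slope <- if (syy > lambda * sxx) Inf else 0
    } else {
      d <- syy - lambda * sxx
      slope <- (d + sqrt(d^2 + 4 * lambda * sxy^2)) / (2 * sxy)
    }
    c(slope = slope, intercept = mean(y) - slope * mean(x))
  }
  fit <- est(x, y)
  jack <- vapply(seq_len(n), function(i) est(x[-i], y[-i]), numeric(2))
  se <- sqrt((n - 1) / n * rowSums((jack - rowMeans(jack))^2))
  tp <- function(estimate, null, se) {
    estimate <- unname(estimate); se <- unname(se)
    if (se == 0) return(if (estimate == null) 1 else 0)
    2 * stats::pt(-abs((estimate - null) / se), df = n - 2)
  }
  resid <- (y - fit["intercept"] - fit["slope"] * x) / sqrt(1 + fit["slope"]^2)
  structure(
    list(slope = unname(fit["slope"]), intercept = unname(fit["intercept"]),
         se_slope = unname(se[1]), se_intercept = unname(se[2]),
         p_slope_vs_1 = tp(fit["slope"], 1, se[1]),
         p_intercept_vs_0 = tp(fit["intercept"], 0, se[2]),
         lambda = lambda, n = n, residuals = unname(resid)),
    class = "deming_fit"
  )
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming fit (lambda = %g, n = %d)\n", x$lambda, x$n))
  cat(sprintf("  slope     %.4f (SE %.4f), p vs 1: %.4g\n",
              x$slope, x$se_slope, x$p_slope_vs_1))
  cat(sprintf("  intercept %.4f (SE %.4f), p vs 0: %.4g\n",
              x$intercept, x$se_intercept, x$p_intercept_vs_0))
  invisible(x)
}

# Vectorized row-wise Pearson correlation between two p x p matrices with NA
# diagonal, excluding the self entry of each row (p - 1 values per row).
row_correlations <- function(a, b) {
  p <- ncol(a)
  a0 <- a; b0 <- b
  diag(a0) <- 0; diag(b0) <- 0
  n <- p - 1
  sa <- rowSums(a0); sb <- rowSums(b0)
  saa <- rowSums(a0^2); sbb <- rowSums(b0^2); sab <- rowSums(a0 * b0)
  va <- saa - sa^2 / n
  vb <- sbb - sb^2 / n
  r <- (sab - sa * sb / n) / sqrt(va * vb)
  r[va <= 0 | vb <= 0] <- NA_real_
  r
}

#' Connectivity fingerprint divergence between groups
#'
#' A scale's fingerprint is the vector of its Fisher-Z correlations with all
#' other scales (its matrix row, self entry excluded). For each scale the two
#' groups' fingerprints are Pearson-correlated and the divergence is
#' 1 - correlation: 0 means identical profiles, values up to 2 mean
#' anti-correlated profiles.
#'
#' @param z_a,z_b `z_network` objects (or Z-matrices) over the same scales.
#' @return Data frame with columns `scale_id`, `fingerprint_r`, `divergence`.
#'   Scales with a zero-variance row get `NA` and are flagged via an attribute
#'   `"degenerate"`.
#' @export
fingerprint_divergence <- function(z_a, z_b) {
  ids <- if (inherits(z_a, "z_network")) z_a$scale_ids else colnames(z_a)
  if (inherits(z_a, "z_network")) z_a <- z_a$z
  if (inherits(z_b, "z_network")) z_b <- z_b$z
  if (!identical(dim(z_a), dim(z_b))) stop("Z-matrices differ in dimension")
  r <- row_correlations(z_a, z_b)
  out <- data.frame(scale_id = ids, fingerprint_r = r, divergence = 1 - r,
                    row.names = NULL)
  attr(out, "degenerate") <- ids[is.na(r)]
  out
}

#' Permutation test of nodal degree differences
#'
#' Compares each scale's observed degree difference (group A minus group B)
#' to its null distribution under group-label permutation; p-values are
#' Bonferroni-corrected across the p scales.
#'
#' @param scores Standardized score matrix for all case subjects.
#' @param labels Case-group labels aligned with `scores` rows.
#' @param plan A [permutation_plan()].
#' @param min_n Minimum pairwise-complete sample size.
#' @param null Optional precomputed `null_dist` containing a
#'   `degree_diff` statistic (lets several tests share one stream).
#' @return Data frame per scale: `degree_a`, `degree_b`, `delta`, `p`,
#'   `p_adj`; attribute `"threshold"` holds the Bonferroni alpha.
#' @export
degree_difference_test <- function(scores, labels, plan, min_n = 10,
                                   null = NULL) {
  obs <- observed_z_pair(scores, labels, min_n)
  deg_a <- nodal_degree(obs$a)
  deg_b <- nodal_degree(obs$b)
  delta <- deg_a - deg_b
  if (is.null(null)) {
    null <- null_distribution(scores, labels, plan,
                              statistics = list(degree_diff = stat_degree_diff),
                              min_n = min_n)
  }
  p <- empirical_p(delta, null$values$degree_diff)
  adj <- bonferroni_adjust(p, m = length(p))
  out <- data.frame(scale_id = obs$a$scale_ids, degree_a = deg_a,
                    degree_b = deg_b, delta = delta, p = p,
                    p_adj = adj$p_adj, row.names = NULL)
  attr(out, "threshold") <- adj$threshold
  out
}

#' Permutation test of fingerprint divergence
#'
#' Tests each scale's observed fingerprint divergence against its null
#' distribution under group-label permutation. Nominal p-values are the
#' primary output (matching the per-scale reporting convention); a
#' Bonferroni-adjusted column is reported alongside.
#'
#' @inheritParams degree_difference_test
#' @return Data frame per scale: `fingerprint_r`, `divergence`, `p`, `p_adj`.
#' @export
fingerprint_test <- function(scores, labels, plan, min_n = 10, null = NULL) {
  obs <- observed_z_pair(scores, labels, min_n)
  fp <- fingerprint_divergence(obs$a, obs$b)
  if (is.null(null)) {
    null <- null_distribution(scores, labels, plan,
                              statistics = list(fingerprint_div = stat_fingerprint_div),
                              min_n = min_n)
  }
  p <- empirical_p(fp$divergence, null$values$fingerprint_div)
  adj <- bonferroni_adjust(p, m = nrow(fp))
  fp$p <- p
  fp$p_adj <- adj$p_adj
  attr(fp, "threshold") <- adj$threshold
  fp
}

#' Edge-level follow-up for one divergent scale
#'
#' For a focal scale, compares its Fisher-Z coupling with every partner scale
#' between the groups: observed `z_a`, `z_b`, their difference, and a nominal
#' permutation p-value per edge from the shared permutation stream. A Deming
#' fit of the focal row in group A against group B is attached, mirroring the
#' scatterplot-based follow-up of divergent scales.
#'
#' @param focal Scale id to follow up.
#' @inheritParams degree_difference_test
#' @return Data frame with p - 1 partner rows (`partner`, `z_a`, `z_b`,
#'   `delta`, `p`); attributes `"deming"` (the fit) and `"focal"`.
#' @export
edgewise_for_scale <- function(focal, scores, labels, plan, min_n = 10,
                               null = NULL) {
  obs <- observed_z_pair(scores, labels, min_n)
  ids <- obs$a$scale_ids
  fi <- match(focal, ids)
  if (is.na(fi)) stop("focal scale not found: ", focal)
  row_a <- obs$a$z[fi, -fi]
  row_b <- obs$b$z[fi, -fi]
  delta <- row_a - row_b
  stat <- make_stat_focal_row(fi)
  if (is.null(null)) {
    null <- null_distribution(scores, labels, plan,
                              statistics = list(focal_row = stat),
                              min_n = min_n)
    nm <- null$values$focal_row
  } else {
    nm <- null$values$focal_row
    if (is.null(nm)) stop("supplied null distribution lacks a 'focal_row' statistic")
  }
  p <- empirical_p(delta, nm)
  out <- data.frame(partner = ids[-fi], z_a = row_a, z_b = row_b,
                    delta = delta, p = p, row.names = NULL)
  attr(out, "deming") <- deming_fit(row_a, row_b)
  attr(out, "focal") <- focal
  out
}

#' Correlation between fingerprint divergence and effect-size difference
#'
#' Tests, across scales, whether fingerprint divergence tracks the absolute
#' difference in the two groups' standardized effect sizes: a check that
#' profile divergence and severity differences carry non-redundant
#' information.
#'
#' @param fp Output of [fingerprint_divergence()] or [fingerprint_test()].
#' @param es Output of [effect_sizes()] over the same scales.
#' @return List with `r`, `p` (two-sided test of zero correlation), `n`.
#' @export
divergence_effectsize_corr <- function(fp, es) {
  if (nrow(fp) != nrow(es)) stop("scale sets differ in length")
  es <- es[match(fp$scale_id, es$scale_id), , drop = FALSE]
  if (anyNA(es$scale_id)) stop("scale sets differ")
  x <- abs(es$effect_a - es$effect_b)
  y <- fp$divergence
  ok <- is.finite(x) & is.finite(y)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) stop("zero variance")
  ct <- stats::cor.test(x[ok], y[ok])
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

# Registered statistic functions for the permutation engine -------------------

#' Permutation statistics for network comparisons
#'
#' Functions of a pair of Fisher-Z matrices for use with
#' [null_distribution()]: per-scale degree difference, per-scale fingerprint
#' divergence, absolute mean-edge difference, the two-sample KS distance
#' between edge distributions, the full upper-triangle delta vector, and a
#' factory for a focal scale's per-partner delta row.
#'
#' @param z_a,z_b Fisher-Z matrices with `NA` diagonal.
#' @return Numeric vector of statistic values.
#' @name perm_statistics
NULL

#' @rdname perm_statistics
#' @export
stat_degree_diff <- function(z_a, z_b) nodal_degree(z_a) - nodal_degree(z_b)

#' @rdname perm_statistics
#' @export
stat_fingerprint_div <- function(z_a, z_b) 1 - row_correlations(z_a, z_b)

#' @rdname perm_statistics
#' @export
stat_mean_edge_diff <- function(z_a, z_b) {
  abs(mean(z_a[lower.tri(z_a)]) - mean(z_b[lower.tri(z_b)]))
}

#' @rdname perm_statistics
#' @export
stat_ks_d <- function(z_a, z_b) {
  ks_distance(z_a[lower.tri(z_a)], z_b[lower.tri(z_b)])
}

#' @rdname perm_statistics
#' @export
stat_delta_edges <- function(z_a, z_b) {
  d <- z_a - z_b
  d[lower.tri(d)]
}

#' @rdname perm_statistics
#' @param focal_index Row index of the focal scale.
#' @export
make_stat_focal_row <- function(focal_index) {
  force(focal_index)
  function(z_a, z_b) z_a[focal_index, -focal_index] - z_b[focal_index, -focal_index]
}
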