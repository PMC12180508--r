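#' Permutation plan
#'
#' Fixes the number of group-label permutations and the RNG seed so that every
#' permutation-based test in a run shares one reproducible stream.
#'
#' @param n_perm Number of permutations (default 10000, the study convention).
#' @param seed Integer RNG seed.
#' @return Object of class `perm_plan`.
#' @export
permutation_plan <- function(n_perm = 10000, seed = 1L) {
  if (!is.numeric(n_perm) || n_perm < 1) stop("n_perm must be >= 1")
  structure(list(n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "perm_plan")
}

#' Permute group labels
#'
#' Draws a uniform random permutation of a label vector using the current RNG
#' state; per-label counts are preserved by construction.
#'
#' @param labels Vector of group labels.
#' @return Permuted label vector.
#' @export
permute_labels <- function(labels) {
  labels[sample.int(length(labels))]
}

#' Null distributions of network statistics under group-label permutation
#'
#' The engine for all permutation inference. Case subjects keep their own
#' control-referenced standardized scores (controls are group-specific, so
#' re-standardization under relabeling is not defined); their case-group
#' labels are shuffled, both pseudo-groups' correlation networks are rebuilt
#' from the score rows, Fisher-Z transformed, and each registered statistic is
#' evaluated on the pair of Z-matrices. A permutation that drops any scale
#' pair below `min_n` pairwise-complete observations in either pseudo-group is
#' redrawn (missingness travels with subjects), up to `10 * n_perm` draws.
#'
#' @param scores Numeric matrix of standardized scores for all case subjects
#'   (rows aligned with `labels`).
#' @param labels Character/factor vector of observed case-group labels, two
#'   distinct values.
#' @param plan A [permutation_plan()].
#' @param statistics Named list of functions `f(z_a, z_b)` each returning a
#'   numeric vector; `z_a`/`z_b` are Fisher-Z matrices with `NA` diagonal.
#' @param min_n Minimum pairwise-complete sample size per pseudo-group.
#' @return Object of class `null_dist`: list with `values` (named list of
#'   `n_perm x length(statistic)` matrices), `n_redraws`, `plan`, `labels`.
#' @export
null_distribution <- function(scores, labels, plan, statistics, min_n = 10) {
  stopifnot(inherits(plan, "perm_plan"), is.list(statistics),
            !is.null(names(statistics)))
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must contain exactly two groups")
  if (length(labels) != nrow(scores)) stop("labels must match score rows")

  set.seed(plan$seed)
  out <- NULL
  n_redraws <- 0L
  max_draws <- 10L * plan$n_perm
  draws <- 0L
  k <- 1L
  while (k <= plan$n_perm) {
    if (draws >= max_draws) {
      stop("exceeded ", max_draws, " permutation draws; too many degenerate ",
           "permutations (min_n = ", min_n, ")")
    }
    perm <- permute_labels(labels)
    draws <- draws + 1L
    z_a <- cor_z_fast(scores[perm == lev[1], , drop = FALSE], min_n)
    z_b <- cor_z_fast(scores[perm == lev[2], , drop = FALSE], min_n)
    if (is.null(z_a) || is.null(z_b)) {
      n_redraws <- n_redraws + 1L
      next
    }
    vals <- lapply(statistics, function(f) as.numeric(f(z_a, z_b)))
    if (is.null(out)) {
      out <- lapply(vals, function(v) matrix(NA_real_, plan$n_perm, length(v)))
      names(out) <- names(statistics)
    }
    for (s in names(vals)) out[[s]][k, ] <- vals[[s]]
    k <- k + 1L
  }
  structure(list(values = out, n_redraws = n_redraws, plan = plan,
                 labels = labels), class = "null_dist")
}

#' Empirical permutation p-value
#'
#' Two-sided on absolute values: the proportion of null statistic values whose
#' magnitude is at least the observed magnitude (ties count against
#' rejection). With `smoothed = TRUE` the estimate is (count + 1)/(n_perm + 1),
#' which avoids exact-zero p-values.
#'
#' @param observed Numeric vector of observed statistics (length m).
#' @param null Numeric matrix (n_perm x m) or vector (m = 1) of null values.
#' @param smoothed Add-one smoothing flag (default `FALSE`, the plain count
#'   formula).
#' @return Numeric vector of p-values, length m.
#' @export
empirical_p <- function(observed, null, smoothed = FALSE) {
  if (is.null(dim(null))) null <- matrix(null, ncol = 1)
  if (length(observed) != ncol(null)) {
    stop("observed length must equal the number of null columns")
  }
  n <- nrow(null)
  counts <- colSums(abs(null) >= matrix(abs(observed), n, length(observed),
                                        byrow = TRUE))
  if (smoothed) (counts + 1) / (n + 1) else counts / n
}

#' Bonferroni correction
#'
#' @param p Vector of nominal p-values.
#' @param m Number of comparisons (default `length(p)`).
#' @param alpha Family-wise alpha (default 0.05).
#' @return List with `p_adj` (`min(1, p * m)`), `threshold` (`alpha / m`), `m`
#'   and `alpha`.
#' @export
bonferroni_adjust <- function(p, m = length(p), alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  list(p_adj = pmin(1, p * m), threshold = alpha / m, m = m, alpha = alpha)
}

# Observed z-networks for the two case groups from a combined score matrix.
observed_z_pair <- function(scores, labels, min_n = 10) {
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must contain exactly two groups")
  make <- function(g) {
    fisher_z(correlation_network(scores[labels == g, , drop = FALSE],
                                 min_n = min_n, group = g))
  }
  list(a = make(lev[1]), b = make(lev[2]), groups = lev)
}
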