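#' Gaussian weighted stochastic block model fit
#'
#' Clusters the nodes of a fully weighted, undirected network (e.g. a Fisher-Z
#' correlation matrix or a between-group delta matrix) so that edge weights
#' depend only on the cluster pair of their endpoints:
#' \deqn{x_{ij} \mid g_i = r, g_j = s \sim N(\mu_{rs}, \sigma^2).}
#' Because both the edge-weight means within and between clusters are modeled,
#' the WSBM detects assortative as well as non-assortative (e.g.
#' core-periphery) structure. Fitting is by variational EM with a mean-field
#' posterior over node assignments: node responsibilities are updated one node
#' at a time by exact coordinate ascent, and (mu, sigma^2, mixing
#' proportions) by weighted maximum likelihood, so the evidence lower bound is
#' non-decreasing. Multiple restarts (spectral initialization plus random
#' label draws) guard against local optima; the best final lower bound wins.
#'
#' @param m Symmetric p x p numeric matrix with masked (`NA`) or unit
#'   diagonal; also accepts `z_network` / `delta_matrix` objects. The diagonal
#'   is excluded from the likelihood entirely.
#' @param K Number of clusters (1 <= K <= p).
#' @param n_restarts Restarts (default 10); the first uses spectral
#'   initialization, the rest random labels.
#' @param seed Optional RNG seed for reproducible restarts.
#' @param tol Relative ELBO convergence tolerance (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 200).
#' @param per_block_variance If `TRUE`, each block pair gets its own variance
#'   instead of the default single shared sigma^2.
#' @return Object of class `wsbm_model`: `K` (clusters actually retained),
#'   `labels` (named hard assignments, ties toward the lowest index), `mu`
#'   (K x K block-mean matrix recomputed at the hard labels, i.e. the
#'   closed-form per-block sample means), `sigma2`, `pi`, `icl`, `elbo`,
#'   `elbo_trace`, `tau` (soft assignments), `restarts_used`, `converged`,
#'   `pruned` (clusters dropped for vanishing responsibility).
#' @export
wsbm_fit <- function(m, K, n_restarts = 10, seed = NULL, tol = 1e-8,
                     max_iter = 200, per_block_variance = FALSE) {
  m <- as_weight_matrix(m)
  p <- ncol(m)
  if (K > p) stop("K must not exceed the number of nodes (", p, ")")
  if (K < 1) stop("K must be >= 1")
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (rs in seq_len(n_restarts)) {
    init <- if (rs == 1) init_spectral(m, K) else init_random(p, K)
    fit <- wsbm_em(m, K, init, tol, max_iter, per_block_variance)
    if (is.null(best) || fit$elbo > best$elbo) best <- fit
    if (K == 1) break
  }
  finalize_wsbm(m, best, n_restarts)
}

as_weight_matrix <- function(m) {
  if (inherits(m, "z_network")) m <- m$z
  if (inherits(m, "delta_matrix")) m <- m$d
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("weight matrix must be square")
  if (is.null(colnames(m))) {
    colnames(m) <- rownames(m) <- paste0("v", seq_len(ncol(m)))
  }
  off <- m[row(m) != col(m)]
  if (any(!is.finite(off))) stop("off-diagonal weights must be finite")
  diag(m) <- 0
  m
}

init_spectral <- function(m, K) {
  p <- ncol(m)
  if (K == 1) return(rep(1L, p))
  eg <- eigen(m, symmetric = TRUE)
  ord <- order(abs(eg$values), decreasing = TRUE)[seq_len(K)]
  V <- eg$vectors[, ord, drop = FALSE]
  km <- tryCatch(
    suppressWarnings(stats::kmeans(V, centers = K, nstart = 8, iter.max = 50)),
    error = function(e) NULL
  )
  if (is.null(km)) return(init_random(p, K))
  km$cluster
}

init_random <- function(p, K) {
  lab <- sample.int(K, p, replace = TRUE)
  lab[sample.int(p, K)] <- seq_len(K)   # guarantee every cluster seeded
  lab
}

# Variational EM for the undirected Gaussian SBM. `init` is a hard label
# vector; responsibilities start near one-hot (0.95 mass on the init label).
wsbm_em <- function(m, K, init, tol, max_iter, per_block_variance) {
  p <- ncol(m)
  M <- m
  M2 <- m^2
  N <- matrix(1, p, p); diag(N) <- 0
  tau <- matrix(0.05 / max(K - 1, 1), p, K)
  tau[cbind(seq_len(p), init)] <- if (K == 1) 1 else 0.95
  sigma_floor <- 1e-10
  elbo_trace <- numeric(0)
  pruned <- 0L
  converged <- FALSE

  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    ## M-step: closed-form weighted ML
    Wm <- crossprod(tau, N %*% tau)
    Sm <- crossprod(tau, M %*% tau)
    Qm <- crossprod(tau, M2 %*% tau)
    mu <- ifelse(Wm > 1e-12, Sm / Wm, 0)
    rss <- Qm - 2 * mu * Sm + mu^2 * Wm
    if (per_block_variance) {
      sig2 <- ifelse(Wm > 1e-12, rss / Wm, 1)
      sig2 <- pmax(sig2, sigma_floor)
    } else {
      sig2 <- matrix(max(sum(rss) / sum(Wm), sigma_floor), K, K)
    }
    pi_k <- pmax(colMeans(tau), 1e-12)
    pi_k <- pi_k / sum(pi_k)

    ## E-step: exact coordinate ascent, one node at a time
    A <- -1 / (2 * sig2)
    B <- mu / sig2
    C <- -mu^2 / (2 * sig2) - 0.5 * log(2 * pi * sig2)
    P2 <- M2 %*% tau
    P1 <- M %*% tau
    P0 <- N %*% tau
    logpi <- log(pi_k)
    for (i in seq_len(p)) {
      eta <- logpi + A %*% P2[i, ] + B %*% P1[i, ] + C %*% P0[i, ]
      eta <- eta - max(eta)
      new_tau <- exp(eta) / sum(exp(eta))
      dt <- new_tau - tau[i, ]
      if (any(dt != 0)) {
        P2 <- P2 + tcrossprod(M2[, i], dt)
        P1 <- P1 + tcrossprod(M[, i], dt)
        P0 <- P0 + tcrossprod(N[, i], dt)
        tau[i, ] <- new_tau
      }
    }

    ## prune clusters whose total responsibility has vanished
    mass <- colSums(tau)
    if (any(mass < 1e-6) && K > 1) {
      keep <- mass >= 1e-6
      tau <- tau[, keep, drop = FALSE]
      tau <- tau / rowSums(tau)
      pruned <- pruned + sum(!keep)
      K <- ncol(tau)
      elbo_trace <- numeric(0)   # refit at reduced K: trace restarts
      next
    }

    elbo <- wsbm_elbo(tau, pi_k, mu, sig2, M, M2, N)
    elbo_trace <- c(elbo_trace, elbo)
    nt <- length(elbo_trace)
    if (nt >= 2 &&
        (elbo_trace[nt] - elbo_trace[nt - 1]) <
          tol * (abs(elbo_trace[nt - 1]) + 1)) {
      converged <- TRUE
      break
    }
  }
  list(tau = tau, pi = pi_k, mu = mu, sigma2 = sig2, K = K,
       elbo = elbo_trace[length(elbo_trace)], elbo_trace = elbo_trace,
       converged = converged, pruned = pruned,
       per_block_variance = per_block_variance)
}

wsbm_elbo <- function(tau, pi_k, mu, sig2, M, M2, N) {
  Wm <- crossprod(tau, N %*% tau)
  Sm <- crossprod(tau, M %*% tau)
  Qm <- crossprod(tau, M2 %*% tau)
  edge_ll <- 0.5 * sum(-Qm / (2 * sig2) + mu * Sm / sig2 -
                         mu^2 * Wm / (2 * sig2) -
                         0.5 * log(2 * pi * sig2) * Wm)
  tl <- tau * log(tau)
  tl[tau == 0] <- 0
  edge_ll + sum(tau %*% log(pi_k)) - sum(tl)
}

finalize_wsbm <- function(m, fit, n_restarts) {
  p <- ncol(m)
  labels <- max.col(fit$tau, ties.method = "first")
  used <- sort(unique(labels))
  labels <- match(labels, used)           # compact to 1..K with no empties
  K <- length(used)
  tau <- fit$tau[, used, drop = FALSE]
  tau <- tau / rowSums(tau)
  mu <- block_means(m, labels)
  sig2_hat <- hard_sigma2(m, labels, mu)
  pi_hat <- tabulate(labels, K) / p
  names(labels) <- colnames(m)
  structure(
    list(K = K, labels = labels, mu = mu, sigma2 = sig2_hat, pi = pi_hat,
         icl = wsbm_icl(m, labels, mu, sig2_hat, pi_hat),
         elbo = fit$elbo, elbo_trace = fit$elbo_trace, tau = tau,
         restarts_used = n_restarts, converged = fit$converged,
         pruned = fit$pruned,
         per_block_variance = fit$per_block_variance),
    class = "wsbm_model"
  )
}

hard_sigma2 <- function(m, labels, mu) {
  lo <- lower.tri(m)
  x <- m[lo]
  idx <- which(lo, arr.ind = TRUE)
  mu_e <- mu[cbind(labels[idx[, 2]], labels[idx[, 1]])]
  max(mean((x - mu_e)^2), 1e-10)
}

# Integrated classification likelihood at the hard assignment: completed-data
# log-likelihood minus the standard Gaussian-SBM penalties for the edge
# parameters (K(K+1)/2 block means + 1 shared variance, on p(p-1)/2 edges)
# and the mixing proportions (K - 1 free parameters, on p nodes).
wsbm_icl <- function(m, labels, mu, sig2, pi_hat) {
  p <- ncol(m)
  K <- max(labels)
  lo <- lower.tri(m)
  x <- m[lo]
  idx <- which(lo, arr.ind = TRUE)
  mu_e <- mu[cbind(labels[idx[, 2]], labels[idx[, 1]])]
  ll_edges <- sum(stats::dnorm(x, mu_e, sqrt(sig2), log = TRUE))
  ll_nodes <- sum(log(pi_hat[labels]))
  n_edges <- p * (p - 1) / 2
  ll_edges + ll_nodes -
    0.5 * (K * (K + 1) / 2 + 1) * log(n_edges) -
    0.5 * (K - 1) * log(p)
}

#' @export
print.wsbm_model <- function(x, ...) {
  cat(sprintf("wsbm_model: K = %d clusters over %d nodes | ICL %.2f | ELBO %.2f\n",
              x$K, length(x$labels), x$icl, x$elbo))
  cat("  sizes:", paste(tabulate(x$labels, x$K), collapse = ", "),
      if (x$pruned > 0) sprintf("| %d cluster(s) pruned", x$pruned) else "", "\n")
  invisible(x)
}

#' Select the number of WSBM clusters by ICL
#'
#' Fits the Gaussian WSBM for every K in `k_range` and returns the solution
#' maximizing the integrated classification likelihood, with the full
#' ICL-versus-K table attached as the `icl_table` element.
#'
#' @inheritParams wsbm_fit
#' @param k_range Candidate cluster counts (default 1:10).
#' @return The best `wsbm_model`, with `icl_table` (data frame `K_requested`,
#'   `K_effective`, `icl`, `elbo`, `converged`).
#' @export
select_k <- function(m, k_range = 1:10, n_restarts = 10, seed = NULL,
                     tol = 1e-8, max_iter = 200, per_block_variance = FALSE) {
  if (length(k_range) == 0) stop("k_range must not be empty")
  m <- as_weight_matrix(m)
  if (!is.null(seed)) set.seed(seed)
  fits <- lapply(k_range, function(K) {
    wsbm_fit(m, K, n_restarts = n_restarts, seed = NULL, tol = tol,
             max_iter = max_iter, per_block_variance = per_block_variance)
  })
  icl_table <- data.frame(
    K_requested = k_range,
    K_effective = vapply(fits, function(f) f$K, integer(1)),
    icl = vapply(fits, function(f) f$icl, numeric(1)),
    elbo = vapply(fits, function(f) f$elbo, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1))
  )
  best <- fits[[which.max(icl_table$icl)]]
  best$icl_table <- icl_table
  best
}

#' Observed block means on a fixed partition
#'
#' For each unique cluster pair (r <= s), the mean of the matrix entries over
#' all node pairs (i != j) with clusters \{r, s\}, diagonal excluded. A
#' within-cluster block of a single-member cluster has no edges and is
#' reported as `NA`.
#'
#' @param m Symmetric p x p matrix (or network object).
#' @param labels Integer cluster labels of the p nodes.
#' @return K x K symmetric matrix of block mean edge weights.
#' @export
block_means <- function(m, labels) {
  m <- as_weight_matrix(m)
  K <- max(labels)
  lo <- lower.tri(m)
  x <- m[lo]
  idx <- which(lo, arr.ind = TRUE)
  r <- pmin(labels[idx[, 2]], labels[idx[, 1]])
  s <- pmax(labels[idx[, 2]], labels[idx[, 1]])
  bid <- (s - 1) * s / 2 + r
  nb <- K * (K + 1) / 2
  sums <- rowsum_safe(x, bid, nb)
  counts <- rowsum_safe(rep(1, length(x)), bid, nb)
  means <- ifelse(counts > 0, sums / counts, NA_real_)
  out <- matrix(NA_real_, K, K)
  pair <- block_pairs(K)
  out[cbind(pair$r, pair$s)] <- means[pair$id]
  out[cbind(pair$s, pair$r)] <- means[pair$id]
  out
}

# Unique cluster pairs r <= s with the triangular index id = s(s-1)/2 + r.
block_pairs <- function(K) {
  s <- rep(seq_len(K), seq_len(K))
  r <- unlist(lapply(seq_len(K), seq_len))
  data.frame(r = r, s = s, id = (s - 1) * s / 2 + r)
}

rowsum_safe <- function(x, bid, nb) {
  out <- numeric(nb)
  agg <- rowsum(x, bid)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Permutation test of block mean edge strength
#'
#' Tests, for each block of the observed WSBM partition of the delta matrix,
#' whether its mean edge strength (mean between-group difference in Fisher-Z
#' coupling, diagonal excluded) is more extreme than expected under
#' group-label permutation. The partition is held fixed: each permutation
#' rebuilds both groups' networks, forms the null delta matrix, and computes
#' null block means for the same edge sets. Bonferroni correction is across
#' the K(K+1)/2 unique blocks.
#'
#' @param scores Standardized score matrix for all case subjects.
#' @param labels Case-group labels aligned with `scores` rows.
#' @param scale_clusters Integer cluster labels of the scales, from the
#'   observed delta-matrix WSBM fit.
#' @param plan A [permutation_plan()].
#' @param min_n Minimum pairwise-complete sample size.
#' @param null Optional precomputed `null_dist` containing a `block_means`
#'   statistic built with [make_stat_block_means()].
#' @return Data frame with one row per unique block: `r`, `s`, `n_edges`,
#'   `mean_edge`, `direction`, `p`, `p_adj`; attribute `"threshold"`.
#' @export
block_permutation_test <- function(scores, labels, scale_clusters, plan,
                                   min_n = 10, null = NULL) {
  obs <- observed_z_pair(scores, labels, min_n)
  d_obs <- obs$a$z - obs$b$z
  K <- max(scale_clusters)
  pair <- block_pairs(K)
  bm_obs <- block_means(d_obs, scale_clusters)
  obs_vec <- bm_obs[cbind(pair$r, pair$s)]
  counts <- block_edge_counts(scale_clusters)
  stat <- make_stat_block_means(scale_clusters)
  if (is.null(null)) {
    null <- null_distribution(scores, labels, plan,
                              statistics = list(block_means = stat),
                              min_n = min_n)
  }
  nm <- null$values$block_means
  if (is.null(nm)) stop("supplied null distribution lacks a 'block_means' statistic")
  p <- rep(NA_real_, length(obs_vec))
  defined <- !is.na(obs_vec)
  p[defined] <- empirical_p(obs_vec[defined], nm[, defined, drop = FALSE])
  adj <- bonferroni_adjust(p, m = nrow(pair))
  out <- data.frame(
    r = pair$r, s = pair$s, n_edges = counts,
    mean_edge = obs_vec, direction = sign(obs_vec),
    p = p, p_adj = adj$p_adj, row.names = NULL
  )
  attr(out, "threshold") <- adj$threshold
  out
}

block_edge_counts <- function(labels) {
  K <- max(labels)
  sizes <- tabulate(labels, K)
  pair <- block_pairs(K)
  ifelse(pair$r == pair$s,
         sizes[pair$r] * (sizes[pair$r] - 1) / 2,
         sizes[pair$r] * sizes[pair$s])
}

#' Block-mean statistic factory for the permutation engine
#'
#' Returns a function of two Fisher-Z matrices computing the vector of null
#' delta-matrix block means on the fixed scale partition, in unique-block
#' order (1,1), (1,2), (2,2), (1,3), ...
#'
#' @param scale_clusters Integer cluster labels of the scales.
#' @return Function `f(z_a, z_b)` for [null_distribution()].
#' @export
make_stat_block_means <- function(scale_clusters) {
  K <- max(scale_clusters)
  p <- length(scale_clusters)
  lo <- lower.tri(matrix(0, p, p))
  idx <- which(lo, arr.ind = TRUE)
  r <- pmin(scale_clusters[idx[, 2]], scale_clusters[idx[, 1]])
  s <- pmax(scale_clusters[idx[, 2]], scale_clusters[idx[, 1]])
  bid <- (s - 1) * s / 2 + r
  nb <- K * (K + 1) / 2
  counts <- rowsum_safe(rep(1, length(bid)), bid, nb)
  function(z_a, z_b) {
    d <- z_a - z_b
    sums <- rowsum_safe(d[lo], bid, nb)
    ifelse(counts > 0, sums / counts, NA_real_)
  }
}

#' Per-group WSBM and partition comparison
#'
#' Applies the WSBM with ICL selection to a single group's Fisher-Z matrix —
#' the complementary view where each group's correlation architecture is
#' clustered separately and the resulting partitions compared.
#'
#' @param z A `z_network` (or weight matrix).
#' @inheritParams select_k
#' @return A `wsbm_model` (with `icl_table`).
#' @export
per_group_wsbm <- function(z, k_range = 1:10, n_restarts = 10, seed = NULL,
                           tol = 1e-8, max_iter = 200) {
  select_k(z, k_range = k_range, n_restarts = n_restarts, seed = seed,
           tol = tol, max_iter = max_iter)
}

#' Compare two partitions of the same node set
#'
#' @param labels_a,labels_b Cluster label vectors over identical nodes.
#' @return List with `crosstab` (contingency table) and `ari` (adjusted Rand
#'   index, via \pkg{mclust}).
#' @export
compare_partitions <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  list(crosstab = table(a = labels_a, b = labels_b),
       ari = mclust::adjustedRandIndex(labels_a, labels_b))
}

#' Export the cluster-level network as GraphML
#'
#' Builds a graph whose nodes are WSBM clusters (sized by weighted degree)
#' and whose edges carry the block mean edge strengths and a significance
#' flag, then writes it as GraphML.
#'
#' @param block_test Output of [block_permutation_test()].
#' @param path Output GraphML path.
#' @param alpha Nominal significance threshold for the edge flag (default .05).
#' @return Invisibly, the igraph object.
#' @export
export_block_graphml <- function(block_test, path, alpha = 0.05) {
  K <- max(block_test$s)
  edges <- block_test[!is.na(block_test$mean_edge), , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$r, to = edges$s,
               weight = edges$mean_edge, p = edges$p,
               significant = !is.na(edges$p) & edges$p < alpha),
    directed = FALSE,
    vertices = data.frame(name = seq_len(K))
  )
  strength <- igraph::strength(g, weights = abs(igraph::E(g)$weight))
  igraph::V(g)$weighted_degree <- strength
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
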