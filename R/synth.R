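#' Synthetic cohort specification
#'
#' Defines a four-group cohort generator based on a cluster-structured factor
#' model. Each subject draws one latent factor per scale cluster from
#' MVN(0, Phi_g) — Phi_g being the group-specific inter-cluster correlation
#' matrix — and each scale loads on its cluster's factor:
#' \deqn{score_{js} = \delta_{jg} + slope_{inst(j)} (age_s - \bar{age}) +
#'       \lambda_j u_{c(j)} + \epsilon,\quad \epsilon \sim N(0, \sigma_j^2).}
#' Ages are uniform on `age_range`; missingness is MCAR at instrument
#' granularity (a subject misses a whole instrument, mirroring
#' age-applicability-driven missingness in questionnaire batteries).
#' The implied population inter-scale correlation is
#' \eqn{\lambda_j \lambda_k \Phi_{c(j)c(k)} /
#'      \sqrt{(\lambda_j^2+\sigma_j^2)(\lambda_k^2+\sigma_k^2)}}.
#'
#' @param p Number of scales.
#' @param instruments Integer/character vector of length p mapping scales to
#'   instruments.
#' @param clusters Integer vector of length p mapping scales to the C latent
#'   clusters.
#' @param loadings Per-scale factor loadings in (0, 1].
#' @param noise_sd Per-scale residual SDs (> 0).
#' @param phi_a,phi_b,phi_ctrl C x C inter-cluster correlation matrices (unit
#'   diagonal, positive semidefinite) for case group A, case group B, and the
#'   control groups.
#' @param mean_shift p x 2 matrix of per-scale mean shifts for the two case
#'   groups (control-referenced impairment effects).
#' @param age_slope Per-instrument linear age slopes (named by instrument).
#' @param age_range Length-2 vector of age bounds in years.
#' @param group_sizes Named integer vector with entries `case_a`, `case_b`,
#'   `control_a`, `control_b`.
#' @param completeness Per-instrument probability that a subject completes
#'   the instrument, in (0, 1].
#' @param polarity Per-scale polarity flags (+1/-1); scales with -1 are
#'   written on the raw scale with inverted sign (higher raw = better),
#'   exercising the standardization-time inversion.
#' @param seed Integer seed for [generate_cohort()].
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(p, instruments, clusters, loadings, noise_sd,
                       phi_a, phi_b, phi_ctrl, mean_shift = NULL,
                       age_slope = NULL, age_range = c(5, 25),
                       group_sizes = c(case_a = 100, case_b = 100,
                                       control_a = 80, control_b = 80),
                       completeness = NULL, polarity = NULL, seed = 1L) {
  stopifnot(length(instruments) == p, length(clusters) == p,
            length(loadings) == p, length(noise_sd) == p)
  C <- max(clusters)
  for (nm in c("phi_a", "phi_b", "phi_ctrl")) {
    phi <- get(nm)
    if (!isTRUE(all.equal(phi, t(phi))) || !all(abs(diag(phi) - 1) < 1e-8)) {
      stop(nm, " must be symmetric with unit diagonal")
    }
    if (min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop(nm, " is not positive semidefinite")
    }
  }
  if (any(loadings <= 0 | loadings > 1)) stop("loadings must lie in (0, 1]")
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0")
  if (is.null(mean_shift)) mean_shift <- matrix(0, p, 2)
  instruments <- as.character(instruments)
  if (is.null(age_slope)) {
    age_slope <- stats::setNames(rep(0, length(unique(instruments))),
                                 unique(instruments))
  }
  if (is.null(completeness)) {
    completeness <- stats::setNames(rep(1, length(unique(instruments))),
                                    unique(instruments))
  }
  if (any(completeness <= 0 | completeness > 1)) {
    stop("completeness must lie in (0, 1]")
  }
  if (is.null(polarity)) polarity <- rep(1L, p)
  structure(
    list(p = p, instruments = instruments, clusters = clusters,
         loadings = loadings, noise_sd = noise_sd,
         phi_a = phi_a, phi_b = phi_b, phi_ctrl = phi_ctrl,
         mean_shift = mean_shift, age_slope = age_slope,
         age_range = age_range, group_sizes = group_sizes,
         completeness = completeness, polarity = polarity,
         seed = as.integer(seed)),
    class = "synth_spec"
  )
}

#' Population inter-scale correlation implied by a synthetic spec
#'
#' @param spec A [synth_spec()].
#' @param group `"case_a"`, `"case_b"` or `"control"`.
#' @return p x p correlation matrix.
#' @export
population_correlation <- function(spec, group = c("case_a", "case_b", "control")) {
  group <- match.arg(group)
  phi <- switch(group, case_a = spec$phi_a, case_b = spec$phi_b,
                control = spec$phi_ctrl)
  lam <- spec$loadings
  tot <- sqrt(lam^2 + spec$noise_sd^2)
  R <- (outer(lam, lam) * phi[spec$clusters, spec$clusters]) / outer(tot, tot)
  diag(R) <- 1
  R
}

#' Generate a synthetic cohort
#'
#' Draws the four groups specified by a [synth_spec()] and returns them as a
#' [cohort_table()] ready for the full pipeline. The same spec and seed always
#' produce an identical table.
#'
#' @param spec A [synth_spec()].
#' @return A [cohort_table()].
#' @export
generate_cohort <- function(spec) {
  set.seed(spec$seed)
  inst <- spec$instruments
  inst_levels <- unique(inst)
  groups <- c("case_a", "case_b", "control_a", "control_b")
  phi_of <- list(case_a = spec$phi_a, case_b = spec$phi_b,
                 control_a = spec$phi_ctrl, control_b = spec$phi_ctrl)
  shift_of <- list(case_a = spec$mean_shift[, 1], case_b = spec$mean_shift[, 2],
                   control_a = rep(0, spec$p), control_b = rep(0, spec$p))
  mid_age <- mean(spec$age_range)

  all_scores <- list(); all_subj <- list()
  for (g in groups) {
    n <- spec$group_sizes[[g]]
    phi <- phi_of[[g]]
    L <- chol_psd(phi)
    age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
    u <- matrix(stats::rnorm(n * ncol(phi)), n) %*% L   # n x C, rows ~ MVN(0, phi)
    eps <- matrix(stats::rnorm(n * spec$p), n) *
      matrix(spec$noise_sd, n, spec$p, byrow = TRUE)
    base <- matrix(shift_of[[g]], n, spec$p, byrow = TRUE) +
      outer(age - mid_age, spec$age_slope[inst]) +
      u[, spec$clusters, drop = FALSE] *
        matrix(spec$loadings, n, spec$p, byrow = TRUE) +
      eps
    base <- sweep(base, 2, spec$polarity, `*`)   # polarity -1: higher raw = better
    miss <- matrix(stats::runif(n * length(inst_levels)), n) >
      matrix(spec$completeness[inst_levels], n, length(inst_levels), byrow = TRUE)
    base[miss[, match(inst, inst_levels), drop = FALSE]] <- NA_real_
    rownames(base) <- sprintf("%s_%03d", g, seq_len(n))
    all_scores[[g]] <- base
    all_subj[[g]] <- data.frame(subject_id = rownames(base), group = g, age = age)
  }
  scores <- do.call(rbind, all_scores)
  colnames(scores) <- sprintf("s%02d_i%s", seq_len(spec$p), inst)
  subjects <- do.call(rbind, all_subj)
  rownames(subjects) <- NULL
  scales <- data.frame(
    scale_id = colnames(scores),
    instrument_id = inst,
    domain_label = paste0("cluster", spec$clusters),
    polarity = spec$polarity
  )
  cohort_table(scores, subjects, scales)
}

# Cholesky-like factor for a PSD (possibly rank-deficient) matrix.
chol_psd <- function(phi) {
  ch <- tryCatch(chol(phi), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  eg <- eigen(phi, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  t(eg$vectors %*% diag(sqrt(vals), length(vals)))
}

# Repair a near-correlation matrix: clip eigenvalues at a small positive
# floor and rescale to unit diagonal.
psd_project <- function(phi, floor = 1e-6) {
  eg <- eigen((phi + t(phi)) / 2, symmetric = TRUE)
  if (min(eg$values) >= floor) return(phi)
  vals <- pmax(eg$values, floor)
  m <- eg$vectors %*% diag(vals) %*% t(eg$vectors)
  stats::cov2cor(m)
}

default_phi <- function(C, off = 0.3) {
  phi <- matrix(off, C, C)
  diag(phi) <- 1
  phi
}

#' Null-cohort preset
#'
#' A spec in which both case groups (and the controls) share one inter-cluster
#' correlation matrix, so the case groups are exchangeable: the reference
#' condition for permutation-test calibration.
#'
#' @param p Number of scales (default 20).
#' @param sizes Named group sizes (default 60/60 cases, 60/60 controls).
#' @param seed Seed.
#' @param n_clusters Latent cluster count (default 4).
#' @return A [synth_spec()].
#' @export
preset_null <- function(p = 20,
                        sizes = c(case_a = 60, case_b = 60,
                                  control_a = 60, control_b = 60),
                        seed = 1L, n_clusters = 4) {
  phi <- default_phi(n_clusters)
  synth_spec(
    p = p,
    instruments = rep(paste0("I", 1:4), length.out = p),
    clusters = rep(seq_len(n_clusters), length.out = p),
    loadings = seq(0.4, 0.95, length.out = p),   # heterogeneous nodal degrees
    noise_sd = seq(0.85, 0.4, length.out = p),
    phi_a = phi, phi_b = phi, phi_ctrl = phi,
    group_sizes = sizes,
    seed = seed
  )
}

#' Planted-delta preset
#'
#' Starts from the null preset and plants a between-group difference in
#' inter-cluster coupling: in each named cluster-pair cell the two case
#' groups' Phi entries are moved apart so that the *population* delta matrix
#' (difference of Fisher-Z inter-scale correlations) equals `effect` in the
#' planted cells and 0 elsewhere. Both Phi matrices are projected back to the
#' nearest valid correlation matrix if the shift breaks positive
#' semidefiniteness; the achieved (post-projection) effect is recorded in the
#' `achieved_effect` attribute.
#'
#' @param effect Planted population delta in Fisher-Z units.
#' @param blocks List of length-2 integer vectors naming cluster-pair cells,
#'   e.g. `list(c(1, 2))`.
#' @param p,sizes,seed,n_clusters As in [preset_null()].
#' @return A [synth_spec()] with attribute `achieved_effect`.
#' @export
preset_planted_delta <- function(effect = 0.4, blocks = list(c(1, 2)),
                                 p = 20,
                                 sizes = c(case_a = 150, case_b = 150,
                                           control_a = 100, control_b = 100),
                                 seed = 1L, n_clusters = 4) {
  phi0 <- default_phi(n_clusters)
  lam <- 0.8; sd0 <- 0.6   # constant loadings: uniform planted effect per cell
  spec <- synth_spec(
    p = p,
    instruments = rep(paste0("I", 1:4), length.out = p),
    clusters = rep(seq_len(n_clusters), length.out = p),
    loadings = rep(lam, p), noise_sd = rep(sd0, p),
    phi_a = phi0, phi_b = phi0, phi_ctrl = phi0,
    group_sizes = sizes, seed = seed
  )
  a <- lam^2 / (lam^2 + sd0^2)   # scale-level r = a * phi between clusters
  phi_a <- spec$phi_a; phi_b <- spec$phi_b
  for (cell in blocks) {
    r0 <- a * phi_a[cell[1], cell[2]]
    z0 <- atanh(r0)
    phi_hi <- tanh(z0 + effect / 2) / a
    phi_lo <- tanh(z0 - effect / 2) / a
    if (abs(phi_hi) > 1 || abs(phi_lo) > 1) {
      stop("planted effect pushes Phi outside [-1, 1]; reduce effect")
    }
    phi_a[cell[1], cell[2]] <- phi_a[cell[2], cell[1]] <- phi_hi
    phi_b[cell[1], cell[2]] <- phi_b[cell[2], cell[1]] <- phi_lo
  }
  phi_a2 <- psd_project(phi_a); phi_b2 <- psd_project(phi_b)
  spec$phi_a <- phi_a2
  spec$phi_b <- phi_b2
  achieved <- vapply(blocks, function(cell) {
    atanh(a * phi_a2[cell[1], cell[2]]) - atanh(a * phi_b2[cell[1], cell[2]])
  }, numeric(1))
  attr(spec, "achieved_effect") <- achieved
  attr(spec, "planted_blocks") <- blocks
  spec
}

#' Rewired-scale preset
#'
#' Plants a fingerprint difference: one scale's cluster membership differs
#' between the two case groups (it couples with one cluster's factor in group
#' A and a different cluster's in group B), so its connectivity profile — but
#' not necessarily its overall degree — diverges between groups.
#'
#' Implemented by giving the rewired scale its own singleton cluster whose
#' correlation with the other clusters differs between Phi_a and Phi_b.
#'
#' @param p,sizes,seed As in [preset_null()].
#' @param strength Coupling of the rewired scale's factor to its group-specific
#'   home cluster (default 0.8).
#' @return A [synth_spec()] with attribute `rewired_scale` (its index).
#' @export
preset_rewired_scale <- function(p = 20,
                                 sizes = c(case_a = 150, case_b = 150,
                                           control_a = 100, control_b = 100),
                                 seed = 1L, strength = 0.8) {
  C <- 4
  base <- preset_null(p = p, sizes = sizes, seed = seed, n_clusters = C)
  clusters <- base$clusters
  rew <- p                     # last scale becomes its own cluster C + 1
  clusters[rew] <- C + 1
  mk_phi <- function(home) {
    phi <- default_phi(C + 1)
    phi[C + 1, seq_len(C)] <- phi[seq_len(C), C + 1] <- 0.1
    phi[C + 1, home] <- phi[home, C + 1] <- strength
    psd_project(phi)
  }
  spec <- synth_spec(
    p = p, instruments = base$instruments, clusters = clusters,
    loadings = base$loadings, noise_sd = base$noise_sd,
    phi_a = mk_phi(1), phi_b = mk_phi(3),
    phi_ctrl = psd_project(rbind(cbind(default_phi(C), rep(0.1, C)),
                                 c(rep(0.1, C), 1))),
    group_sizes = sizes, seed = seed
  )
  attr(spec, "rewired_scale") <- rew
  spec
}

#' Paper-scale cohort preset
#'
#' Emulates the structure of the motivating study cohort: 53 scales from 9
#' instruments, 6 latent clusters, case groups of 102 and 64 subjects with
#' age-matched control groups of 74 and 60 (300 subjects in total),
#' instrument-level completeness spread over \[0.65, 0.98\], per-instrument
#' linear age effects, per-scale case effect sizes, two inverted-polarity
#' scales, and inter-cluster coupling that differs between the case groups in
#' several cells.
#'
#' @param seed Seed.
#' @return A [synth_spec()].
#' @export
preset_paperlike <- function(seed = 1L) {
  p <- 53
  inst_sizes <- c(13, 5, 8, 5, 4, 9, 2, 3, 4)   # 9 instruments, sums to 53
  instruments <- rep(paste0("I", seq_along(inst_sizes)), inst_sizes)
  set.seed(seed + 211L)
  clusters <- sort(rep(1:6, length.out = p))
  clusters <- sample(clusters)                  # clusters cut across instruments
  loadings <- stats::runif(p, 0.3, 0.95)
  noise_sd <- stats::runif(p, 0.4, 0.9)
  phi <- default_phi(6, off = 0.35)
  # case groups differ in a few inter-cluster couplings (coordinated delta)
  phi_a <- phi; phi_b <- phi
  phi_a[1, 2] <- phi_a[2, 1] <- 0.55; phi_b[1, 2] <- phi_b[2, 1] <- 0.15
  phi_a[1, 3] <- phi_a[3, 1] <- 0.50; phi_b[1, 3] <- phi_b[3, 1] <- 0.20
  phi_b[5, 6] <- phi_b[6, 5] <- 0.60; phi_a[5, 6] <- phi_a[6, 5] <- 0.20
  phi_a <- psd_project(phi_a); phi_b <- psd_project(phi_b)
  mean_shift <- cbind(stats::runif(p, 0.2, 1.0), stats::runif(p, 0.3, 1.2))
  age_slope <- stats::setNames(stats::runif(9, -0.03, 0.03),
                               unique(instruments))
  completeness <- stats::setNames(stats::runif(9, 0.65, 0.98),
                                  unique(instruments))
  polarity <- rep(1L, p); polarity[c(10, 25)] <- -1L
  synth_spec(
    p = p, instruments = instruments, clusters = clusters,
    loadings = loadings, noise_sd = noise_sd,
    phi_a = phi_a, phi_b = phi_b, phi_ctrl = phi,
    mean_shift = mean_shift, age_slope = age_slope,
    age_range = c(5, 25),
    group_sizes = c(case_a = 102, case_b = 64, control_a = 74, control_b = 60),
    completeness = completeness, polarity = polarity,
    seed = seed
  )
}
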