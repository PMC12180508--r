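# Shared fixtures, built in code at test time.

# Standardize both case groups of a cohort and stack their score rows for the
# permutation engine.
std_pair <- function(tab, min_n = 10) {
  std_a <- standardize_against_controls(tab, "case_a", "control_a")
  std_b <- standardize_against_controls(tab, "case_b", "control_b")
  list(
    std_a = std_a, std_b = std_b,
    scores = rbind(std_a$values, std_b$values),
    labels = c(rep("case_a", nrow(std_a$values)),
               rep("case_b", nrow(std_b$values)))
  )
}

# Hand-built tiny cohort: explicit scores per group, shared age vector.
toy_cohort <- function(case_a, control_a, ages_case = NULL, ages_ctrl = NULL,
                       polarity = NULL) {
  p <- ncol(case_a)
  na <- nrow(case_a); nc <- nrow(control_a)
  if (is.null(ages_case)) ages_case <- seq(6, 20, length.out = na)
  if (is.null(ages_ctrl)) ages_ctrl <- seq(6, 20, length.out = nc)
  if (is.null(polarity)) polarity <- rep(1L, p)
  scores <- rbind(case_a, control_a)
  ids <- c(sprintf("ca%02d", seq_len(na)), sprintf("ct%02d", seq_len(nc)))
  rownames(scores) <- ids
  colnames(scores) <- sprintf("sc%02d", seq_len(p))
  subjects <- data.frame(
    subject_id = ids,
    group = c(rep("case_a", na), rep("control_a", nc)),
    age = c(ages_case, ages_ctrl)
  )
  scales <- data.frame(scale_id = colnames(scores), instrument_id = "I1",
                       domain_label = "toy", polarity = polarity)
  cohort_table(scores, subjects, scales)
}

# Wrap a plain symmetric matrix as a z_network (NA diagonal).
as_z_network <- function(m, group = "g") {
  diag(m) <- NA_real_
  if (is.null(colnames(m))) colnames(m) <- rownames(m) <- paste0("v", seq_len(ncol(m)))
  structure(list(z = m, scale_ids = colnames(m), group = group),
            class = "z_network")
}

# Planted block-structured weight matrix: within-block mean `hi`, between
# `lo`, Gaussian noise `sd` (0 = noiseless).
planted_matrix <- function(labels, hi = 0.6, lo = -0.6, sd = 0) {
  p <- length(labels)
  m <- outer(labels, labels, function(a, b) ifelse(a == b, hi, lo))
  if (sd > 0) {
    e <- matrix(stats::rnorm(p * p, 0, sd), p)
    e[lower.tri(e)] <- t(e)[lower.tri(e)]
    diag(e) <- 0
    m <- m + e
  }
  diag(m) <- NA_real_
  colnames(m) <- rownames(m) <- paste0("v", seq_len(p))
  m
}
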