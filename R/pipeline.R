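#' Default pipeline configuration
#'
#' Every analysis choice the method leaves open surfaces here: the minimum
#' per-group (and pairwise) sample size, the interaction-screen alpha, the
#' permutation count and seed, the WSBM search range and restarts, and the
#' toggles (smoothed p-values, per-block variance, listwise deletion).
#'
#' @param output_dir Where [run_pipeline()] writes its tables.
#' @return Named list of configuration values.
#' @export
default_config <- function(output_dir = "psynetcomp_run") {
  list(
    scores_path = NULL, subjects_path = NULL, scales_path = NULL,
    case_a = "case_a", case_b = "case_b",
    control_a = "control_a", control_b = "control_b",
    min_n = 10,
    alpha_screen = 0.05,
    alpha = 0.05,
    n_perm = 10000,
    seed = 1,
    k_range = 1:10,
    n_restarts = 10,
    smoothed_p = FALSE,
    per_block_variance = FALSE,
    listwise = FALSE,
    edgewise_max_scales = 4,
    output_dir = output_dir
  )
}

#' Run the full network-comparison pipeline
#'
#' Sequences standardization, network construction, nodal-degree and
#' fingerprint comparisons, edge-distribution tests, and delta-matrix WSBM
#' clustering with block-level permutation inference, sharing one permutation
#' stream across all tests. Writes every stage's tables plus a JSON manifest
#' into `config$output_dir`. Identical config and seed produce byte-identical
#' numeric tables.
#'
#' @param config List from [default_config()] (entries may be overridden).
#' @param cohort Optionally, a [cohort_table()] passed directly instead of the
#'   three CSV paths in the config.
#' @return Invisibly, a list with all computed results and `output_dir`.
#' @export
run_pipeline <- function(config = default_config(), cohort = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  if (cfg$n_perm < 1) stop("n_perm must be >= 1")
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 2)
    t0 <<- t1
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(cfg$output_dir, f)

  if (is.null(cohort)) {
    meta <- read_scale_metadata(cfg$scales_path)
    cohort <- read_cohort(cfg$scores_path, cfg$subjects_path, meta)
  }
  report <- validate_cohort(cohort, min_n = cfg$min_n,
                            groups = c(cfg$case_a, cfg$case_b))
  utils::write.csv(report, out("validation_report.csv"), row.names = FALSE)
  if (any(report$flagged)) {
    stop("scale(s) below min_n in a case group: ",
         paste(report$scale_id[report$flagged], collapse = ", "),
         " (see validation_report.csv)")
  }
  tick("validate")

  ## standardization (each case group against its own matched controls)
  methods_a <- standardization_methods(cohort, cfg$case_a, cfg$control_a,
                                       alpha_screen = cfg$alpha_screen,
                                       min_n = cfg$min_n)
  methods_b <- standardization_methods(cohort, cfg$case_b, cfg$control_b,
                                       alpha_screen = cfg$alpha_screen,
                                       min_n = cfg$min_n)
  std_a <- standardize_against_controls(cohort, cfg$case_a, cfg$control_a, methods_a)
  std_b <- standardize_against_controls(cohort, cfg$case_b, cfg$control_b, methods_b)
  ctrl_a <- standardize_against_controls(cohort, cfg$case_a, cfg$control_a,
                                         methods_a, subjects = "control")
  ctrl_b <- standardize_against_controls(cohort, cfg$case_b, cfg$control_b,
                                         methods_b, subjects = "control")
  es <- effect_sizes(std_a, std_b, ctrl_a, ctrl_b)
  utils::write.csv(rbind(cbind(pair = "a", methods_a), cbind(pair = "b", methods_b)),
                   out("standardization_methods.csv"), row.names = FALSE)
  write_scores_csv(std_a, out("standardized_case_a.csv"))
  write_scores_csv(std_b, out("standardized_case_b.csv"))
  utils::write.csv(es, out("effect_sizes.csv"), row.names = FALSE)
  tick("standardize")

  ## per-group networks and delta matrix
  use <- if (cfg$listwise) "listwise" else "pairwise"
  net_a <- correlation_network(std_a, min_n = cfg$min_n, use = use)
  net_b <- correlation_network(std_b, min_n = cfg$min_n, use = use)
  z_a <- fisher_z(net_a); z_b <- fisher_z(net_b)
  delta <- delta_matrix(z_a, z_b)
  write_matrix_csv(net_a, out("correlation_case_a.csv"))
  write_matrix_csv(net_b, out("correlation_case_b.csv"))
  write_matrix_csv(z_a, out("z_case_a.csv"))
  write_matrix_csv(z_b, out("z_case_b.csv"))
  write_matrix_csv(delta, out("delta_matrix.csv"))
  utils::write.csv(upper_triangle(delta), out("delta_edges.csv"), row.names = FALSE)
  tick("networks")

  ## WSBM on the observed delta matrix (labels needed before the shared
  ## permutation stream so block means ride along with the other statistics)
  wsbm <- select_k(delta, k_range = cfg$k_range, n_restarts = cfg$n_restarts,
                   seed = cfg$seed, per_block_variance = cfg$per_block_variance)
  utils::write.csv(data.frame(scale_id = names(wsbm$labels),
                              cluster = unname(wsbm$labels)),
                   out("wsbm_labels.csv"), row.names = FALSE)
  utils::write.csv(wsbm$icl_table, out("wsbm_icl_table.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(K = wsbm$K, icl = wsbm$icl, elbo = wsbm$elbo, sigma2 = wsbm$sigma2,
         mu = wsbm$mu, pi = wsbm$pi, converged = wsbm$converged),
    out("wsbm_model.json"), auto_unbox = TRUE, digits = NA, na = "null")
  tick("wsbm_fit")

  ## one shared permutation stream for every test
  case_rows <- c(rownames(std_a$values), rownames(std_b$values))
  scores <- rbind(std_a$values, std_b$values)
  labels <- c(rep(cfg$case_a, nrow(std_a$values)),
              rep(cfg$case_b, nrow(std_b$values)))
  plan <- permutation_plan(n_perm = cfg$n_perm, seed = cfg$seed)
  statistics <- list(
    degree_diff = stat_degree_diff,
    fingerprint_div = stat_fingerprint_div,
    mean_edge_diff = stat_mean_edge_diff,
    ks_d = stat_ks_d,
    block_means = make_stat_block_means(unname(wsbm$labels))
  )
  null <- null_distribution(scores, labels, plan, statistics, min_n = cfg$min_n)
  tick("permutations")

  ## nodal degree comparison
  deg_test <- degree_difference_test(scores, labels, plan, min_n = cfg$min_n,
                                     null = null)
  congruence <- degree_congruence(deg_test$degree_a, deg_test$degree_b)
  deming <- deming_fit(deg_test$degree_a, deg_test$degree_b)
  deg_test$deming_residual <- deming$residuals
  utils::write.csv(deg_test, out("degree_comparison.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(congruence_r = congruence, slope = deming$slope,
         intercept = deming$intercept, se_slope = deming$se_slope,
         se_intercept = deming$se_intercept,
         p_slope_vs_1 = deming$p_slope_vs_1,
         p_intercept_vs_0 = deming$p_intercept_vs_0,
         bonferroni_threshold = attr(deg_test, "threshold")),
    out("degree_deming.json"), auto_unbox = TRUE, digits = NA)
  tick("degree")

  ## fingerprint divergence + edge-level follow-up of significant scales
  fp <- fingerprint_test(scores, labels, plan, min_n = cfg$min_n, null = null)
  fp$abs_effect_diff <- abs(es$effect_a - es$effect_b)
  utils::write.csv(fp, out("fingerprint_divergence.csv"), row.names = FALSE)
  fp_es <- divergence_effectsize_corr(fp, es)
  focal_ids <- fp$scale_id[order(fp$p, -fp$divergence)]
  focal_ids <- utils::head(focal_ids[fp$p[order(fp$p, -fp$divergence)] < cfg$alpha],
                           cfg$edgewise_max_scales)
  edgewise <- list()
  for (sc in focal_ids) {
    enull <- null_distribution(scores, labels, plan,
                               statistics = list(
                                 focal_row = make_stat_focal_row(
                                   match(sc, fp$scale_id))),
                               min_n = cfg$min_n)
    ew <- edgewise_for_scale(sc, scores, labels, plan, min_n = cfg$min_n,
                             null = enull)
    utils::write.csv(ew, out(paste0("edgewise_", sc, ".csv")), row.names = FALSE)
    edgewise[[sc]] <- ew
  }
  tick("fingerprint")

  ## full edge-distribution comparison
  edge_dist <- edge_distribution_test(scores, labels, plan, min_n = cfg$min_n,
                                      null = null)
  utils::write.csv(edge_dist, out("edge_distribution.csv"), row.names = FALSE)
  tick("edges")

  ## block-level permutation inference on the fixed WSBM partition
  block_test <- block_permutation_test(scores, labels, unname(wsbm$labels),
                                       plan, min_n = cfg$min_n, null = null)
  utils::write.csv(block_test, out("block_test.csv"), row.names = FALSE)
  export_block_graphml(block_test, out("block_network.graphml"),
                       alpha = cfg$alpha)
  tick("blocks")

  manifest <- list(
    package_version = as.character(utils::packageVersion("psynetcomp")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg[setdiff(names(cfg), "output_dir")],
    n_subjects = nrow(cohort$scores),
    n_case = length(case_rows),
    n_scales = ncol(cohort$scores),
    n_edges = ncol(cohort$scores) * (ncol(cohort$scores) - 1) / 2,
    permutation_redraws = null$n_redraws,
    selected_k = wsbm$K,
    stage_seconds = as.list(timings)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(summarize_run(congruence, deming, fp, edge_dist, wsbm, block_test,
                           fp_es, cfg),
             out("summary.txt"))

  invisible(list(
    cohort = cohort, std_a = std_a, std_b = std_b, effect_sizes = es,
    networks = list(a = net_a, b = net_b, z_a = z_a, z_b = z_b, delta = delta),
    degree = deg_test, congruence = congruence, deming = deming,
    fingerprint = fp, fingerprint_effectsize = fp_es, edgewise = edgewise,
    edge_distribution = edge_dist, wsbm = wsbm, block_test = block_test,
    null = null, config = cfg, output_dir = cfg$output_dir
  ))
}

write_scores_csv <- function(std, path) {
  df <- data.frame(subject_id = rownames(std$values), std$values,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

summarize_run <- function(congruence, deming, fp, edge_dist, wsbm, block_test,
                          fp_es, cfg) {
  c(
    "psynetcomp pipeline summary",
    sprintf("degree congruence r = %.3f", congruence),
    sprintf("Deming slope %.3f (p vs 1 = %.3f), intercept %.3f (p vs 0 = %.3f)",
            deming$slope, deming$p_slope_vs_1, deming$intercept,
            deming$p_intercept_vs_0),
    sprintf("fingerprint divergence range %.3f..%.3f; %d scale(s) p < %.2f",
            min(fp$divergence, na.rm = TRUE), max(fp$divergence, na.rm = TRUE),
            sum(fp$p < cfg$alpha, na.rm = TRUE), cfg$alpha),
    sprintf("divergence vs |effect size diff|: r = %.3f (p = %.3f)",
            fp_es$r, fp_es$p),
    sprintf("mean edge z: %.3f vs %.3f (|delta| = %.3f, p = %.3f)",
            edge_dist$mean_a, edge_dist$mean_b, edge_dist$abs_delta_mean,
            edge_dist$p_mean),
    sprintf("KS D = %.3f (permutation p = %.3f); kurtosis %.2f vs %.2f",
            edge_dist$ks_d, edge_dist$p_ks, edge_dist$kurtosis_a,
            edge_dist$kurtosis_b),
    sprintf("WSBM: K = %d clusters (ICL %.1f); %d/%d blocks p < %.2f",
            wsbm$K, wsbm$icl, sum(block_test$p < cfg$alpha, na.rm = TRUE),
            nrow(block_test), cfg$alpha)
  )
}
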