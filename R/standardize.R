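#' Screen an instrument for age-by-group interactions
#'
#' Fits, for every scale of the instrument, a linear model
#' `score ~ age + group + age:group` over the combined case + control
#' subjects. The instrument is assigned the `age_residual` standardization
#' method if any of its scales shows an interaction p-value below
#' `alpha_screen` (the per-instrument rule; set `per_scale = TRUE` to decide
#' scale by scale instead), otherwise `mean_sd`.
#'
#' @param table A [cohort_table()].
#' @param instrument_id Instrument to screen.
#' @param case_group,control_group Group labels to combine.
#' @param alpha_screen Screening alpha (uncorrected, default 0.05).
#' @param min_n Minimum observations required per group per scale.
#' @param per_scale If `TRUE`, return one method per scale instead of one per
#'   instrument.
#' @return A data frame with columns `instrument_id`, `scale_id`, `method`
#'   (`"mean_sd"` or `"age_residual"`) and `interaction_p`. Under the
#'   per-instrument rule all rows of an instrument share one method and
#'   `interaction_p` is the minimum across its scales.
#' @export
detect_age_interaction <- function(table, instrument_id, case_group = "case_a",
                                   control_group = "control_a",
                                   alpha_screen = 0.05, min_n = 10,
                                   per_scale = FALSE) {
  scales <- table$scales$scale_id[table$scales$instrument_id == instrument_id]
  if (length(scales) == 0) stop("unknown instrument_id: ", instrument_id)
  keep <- table$subjects$group %in% c(case_group, control_group)
  age <- table$subjects$age[keep]
  grp <- factor(as.character(table$subjects$group[keep]),
                levels = c(control_group, case_group))
  if (length(unique(age)) < 2) stop("degenerate design: all ages equal")
  p_int <- vapply(scales, function(sc) {
    y <- table$scores[keep, sc]
    ok <- !is.na(y)
    if (sum(ok & grp == case_group) < min_n || sum(ok & grp == control_group) < min_n) {
      return(NA_real_)
    }
    fit <- stats::lm(y ~ age * grp, subset = ok)
    cf <- stats::summary.lm(fit)$coefficients
    row <- grep(":", rownames(cf), fixed = TRUE)
    if (length(row) == 0) return(NA_real_)
    cf[row, "Pr(>|t|)"]
  }, numeric(1))
  if (all(is.na(p_int))) {
    stop("no scale of instrument ", instrument_id,
         " has enough observations in both groups")
  }
  if (per_scale) {
    method <- ifelse(!is.na(p_int) & p_int < alpha_screen, "age_residual", "mean_sd")
    data.frame(instrument_id = instrument_id, scale_id = scales,
               method = method, interaction_p = p_int, row.names = NULL)
  } else {
    pmin_inst <- min(p_int, na.rm = TRUE)
    method <- if (pmin_inst < alpha_screen) "age_residual" else "mean_sd"
    data.frame(instrument_id = instrument_id, scale_id = scales,
               method = method, interaction_p = pmin_inst, row.names = NULL)
  }
}

#' Standardization methods for every instrument
#'
#' Runs [detect_age_interaction()] across all instruments of the battery.
#'
#' @inheritParams detect_age_interaction
#' @return One data frame with a row per scale.
#' @export
standardization_methods <- function(table, case_group = "case_a",
                                    control_group = "control_a",
                                    alpha_screen = 0.05, min_n = 10,
                                    per_scale = FALSE) {
  instruments <- unique(table$scales$instrument_id)
  out <- lapply(instruments, detect_age_interaction, table = table,
                case_group = case_group, control_group = control_group,
                alpha_screen = alpha_screen, min_n = min_n,
                per_scale = per_scale)
  res <- do.call(rbind, out)
  res[match(table$scales$scale_id, res$scale_id), , drop = FALSE]
}

#' Standardize case scores against the matched control group
#'
#' Converts raw case-group scores to control-referenced z-scores, scale by
#' scale. Under `mean_sd` the score is centered and scaled by the control
#' group's observed mean and SD. Under `age_residual` a linear model
#' `score ~ age` is fitted in the controls alone and the case score is
#' expressed as its deviation from the control prediction at the case
#' subject's age, divided by the control residual standard error (n - 2
#' denominator). Scoring polarity is then applied so that higher z always
#' means greater impairment.
#'
#' @param table A [cohort_table()].
#' @param case_group,control_group Which case group and its matched controls.
#' @param methods Per-scale method table from [standardization_methods()];
#'   if `NULL`, `mean_sd` is used everywhere.
#' @param subjects `"case"` (default) standardizes the case group;
#'   `"control"` standardizes the control group against itself with the same
#'   reference parameters (used for effect-size models).
#' @return An object of class `std_scores`: list with `values` (subjects x
#'   scales z-matrix), `group`, `reference`, `ages`, and `methods`.
#' @export
standardize_against_controls <- function(table, case_group = "case_a",
                                         control_group = "control_a",
                                         methods = NULL,
                                         subjects = c("case", "control")) {
  subjects <- match.arg(subjects)
  if (is.null(methods)) {
    methods <- data.frame(scale_id = table$scales$scale_id, method = "mean_sd",
                          interaction_p = NA_real_)
  }
  method_of <- methods$method[match(table$scales$scale_id, methods$scale_id)]
  ctrl <- group_scores(table, control_group)
  ctrl_age <- group_ages(table, control_group)
  target_group <- if (subjects == "case") case_group else control_group
  raw <- group_scores(table, target_group)
  target_age <- group_ages(table, target_group)

  z <- raw
  for (j in seq_len(ncol(raw))) {
    cj <- ctrl[, j]
    ok <- !is.na(cj)
    if (sum(ok) < 3) stop("fewer than 3 control observations for scale ",
                          colnames(raw)[j])
    if (identical(method_of[j], "age_residual")) {
      fit <- stats::lm(cj[ok] ~ ctrl_age[ok])
      co <- stats::coef(fit)
      rse <- sqrt(sum(stats::residuals(fit)^2) / (sum(ok) - 2))
      if (!is.finite(rse) || rse <= 0) {
        stop("zero control residual variance for scale ", colnames(raw)[j])
      }
      pred <- co[1] + co[2] * target_age
      z[, j] <- (raw[, j] - pred) / rse
    } else {
      m <- mean(cj[ok])
      s <- stats::sd(cj[ok])
      if (!is.finite(s) || s <= 0) {
        stop("zero control variance for scale ", colnames(raw)[j])
      }
      z[, j] <- (raw[, j] - m) / s
    }
  }
  z <- sweep(z, 2, table$scales$polarity, `*`)
  structure(
    list(values = z, group = target_group, reference = control_group,
         ages = target_age, methods = methods),
    class = "std_scores"
  )
}

#' @export
print.std_scores <- function(x, ...) {
  cat("std_scores:", nrow(x$values), "subjects x", ncol(x$values),
      "scales | group", x$group, "referenced to", x$reference, "\n")
  invisible(x)
}

#' Per-scale group effect sizes
#'
#' For each case group and each scale, fits an ordinary least squares model of
#' the control-referenced standardized score on a 0/1 group indicator over the
#' case + matched-control subjects; the group coefficient is the standardized
#' effect size (control-SD units).
#'
#' @param std_a,std_b `std_scores` for the two case groups.
#' @param ctrl_a,ctrl_b `std_scores` for the two control groups (each
#'   standardized against itself, `subjects = "control"`).
#' @return Data frame with columns `scale_id`, `effect_a`, `effect_b`.
#' @export
effect_sizes <- function(std_a, std_b, ctrl_a, ctrl_b) {
  stopifnot(identical(colnames(std_a$values), colnames(std_b$values)))
  one <- function(case, ctrl) {
    vapply(seq_len(ncol(case$values)), function(j) {
      y <- c(case$values[, j], ctrl$values[, j])
      g <- c(rep(1, nrow(case$values)), rep(0, nrow(ctrl$values)))
      ok <- !is.na(y)
      if (sum(ok & g == 1) < 3 || sum(ok & g == 0) < 3) {
        stop("fewer than 3 subjects per arm for scale ", colnames(case$values)[j])
      }
      unname(stats::coef(stats::lm(y ~ g, subset = ok))[2])
    }, numeric(1))
  }
  data.frame(
    scale_id = colnames(std_a$values),
    effect_a = one(std_a, ctrl_a),
    effect_b = one(std_b, ctrl_b),
    row.names = NULL
  )
}
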