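GROUP_LEVELS <- c("case_a", "case_b", "control_a", "control_b")

#' Read scale metadata
#'
#' Parses a CSV describing the questionnaire scales in the battery. Each row is
#' one dimensional measure (scale) belonging to an instrument. The polarity
#' flag marks scales on which a *higher* raw score means *better* functioning
#' (e.g. prosocial or motor-competence scales); such scales are sign-inverted
#' during standardization so that higher always means greater impairment.
#'
#' @param path Path to a CSV with header columns `scale_id`, `instrument_id`,
#'   `domain_label`, `polarity`. Polarity may be given as `+1`/`-1` or as the
#'   strings `"keep"`/`"invert"`.
#' @return A data frame with columns `scale_id`, `instrument_id`,
#'   `domain_label`, `polarity` (integer, +1 or -1).
#' @export
read_scale_metadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("scale_id", "instrument_id", "domain_label", "polarity")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("scale metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  dup <- unique(df$scale_id[duplicated(df$scale_id)])
  if (length(dup) > 0) {
    stop("duplicate scale_id in metadata: ", paste(dup, collapse = ", "))
  }
  df$polarity <- parse_polarity(df$polarity)
  df[, required]
}

parse_polarity <- function(x) {
  out <- rep(NA_integer_, length(x))
  xl <- tolower(trimws(as.character(x)))
  out[xl %in% c("1", "+1", "keep")] <- 1L
  out[xl %in% c("-1", "invert")] <- -1L
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("polarity must be +1, -1, 'keep' or 'invert'; got: ",
         paste(bad, collapse = ", "))
  }
  out
}

#' Construct a cohort table
#'
#' Bundles a subjects-by-scales raw score matrix with subject metadata
#' (group membership, age) and scale metadata into a validated container.
#'
#' @param scores Numeric matrix, subjects in rows (rownames = subject ids),
#'   scales in columns (colnames = scale ids). `NA` marks missing scores.
#' @param subjects Data frame with columns `subject_id`, `group`
#'   (one of `case_a`, `case_b`, `control_a`, `control_b`) and `age` (years).
#' @param scales Data frame as returned by [read_scale_metadata()].
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(scores, subjects, scales) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("scores matrix must carry subject ids as rownames and scale ids as colnames")
  }
  if (!identical(colnames(scores), scales$scale_id)) {
    stop("score columns do not match scale metadata (order and names must agree)")
  }
  if (!identical(rownames(scores), subjects$subject_id)) {
    stop("score rows do not match subject metadata (order and ids must agree)")
  }
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]), collapse = ", "))
  }
  bad_group <- setdiff(unique(as.character(subjects$group)), GROUP_LEVELS)
  if (length(bad_group) > 0) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "))
  }
  if (any(!is.finite(subjects$age)) || any(subjects$age <= 0)) {
    stop("all ages must be finite and > 0")
  }
  subjects$group <- factor(as.character(subjects$group), levels = GROUP_LEVELS)
  structure(
    list(scores = scores, subjects = subjects, scales = scales),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("cohort_table:", nrow(x$scores), "subjects x", ncol(x$scores), "scales\n")
  cat("  groups:", paste(sprintf("%s=%d", levels(x$subjects$group),
                                 tabulate(x$subjects$group, 4)), collapse = ", "), "\n")
  cat("  instruments:", length(unique(x$scales$instrument_id)),
      " | missing cells:", sum(is.na(x$scores)),
      sprintf("(%.1f%%)", 100 * mean(is.na(x$scores))), "\n")
  invisible(x)
}

#' Read a cohort from CSV files
#'
#' @param scores_path Wide CSV: column `subject_id` plus one column per scale.
#'   Empty cells and the string `"NA"` are treated as missing.
#' @param subjects_path CSV with columns `subject_id`, `group`, `age`.
#' @param meta Scale metadata from [read_scale_metadata()]; the score columns
#'   must cover exactly these scales.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(scores_path, subjects_path, meta) {
  raw <- utils::read.csv(scores_path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  subj <- utils::read.csv(subjects_path, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(raw)) stop("scores file lacks a subject_id column")
  for (col in c("subject_id", "group", "age")) {
    if (!col %in% names(subj)) stop("subjects file lacks column ", col)
  }
  missing_scales <- setdiff(meta$scale_id, names(raw))
  if (length(missing_scales) > 0) {
    stop("scores file lacks scale column(s): ", paste(missing_scales, collapse = ", "))
  }
  only_scores <- setdiff(raw$subject_id, subj$subject_id)
  if (length(only_scores) > 0) {
    stop("subject(s) in scores file but not in subjects file: ",
         paste(only_scores, collapse = ", "))
  }
  only_subj <- setdiff(subj$subject_id, raw$subject_id)
  if (length(only_subj) > 0) {
    stop("subject(s) in subjects file but not in scores file: ",
         paste(only_subj, collapse = ", "))
  }
  subj <- subj[match(raw$subject_id, subj$subject_id), , drop = FALSE]
  rownames(subj) <- NULL

  score_cols <- raw[, meta$scale_id, drop = FALSE]
  scores <- vapply(score_cols, parse_score_column, numeric(nrow(raw)))
  if (nrow(raw) == 1L) scores <- matrix(scores, nrow = 1L,
                                        dimnames = list(NULL, meta$scale_id))
  rownames(scores) <- raw$subject_id
  cohort_table(scores, subj, meta)
}

parse_score_column <- function(x) {
  x <- trimws(x)
  miss <- is.na(x) | x == "" | toupper(x) == "NA"
  x[is.na(x)] <- ""
  out <- suppressWarnings(as.numeric(x))
  bad <- !miss & is.na(out)
  if (any(bad)) {
    stop("non-numeric score value(s): ", paste(unique(x[bad]), collapse = ", "))
  }
  out[miss] <- NA_real_
  out
}

#' Write a cohort to CSV files
#'
#' Writes the three tables in the same format [read_cohort()] reads, so that a
#' write/read round trip reproduces scores, missingness and metadata exactly.
#'
#' @param table A [cohort_table()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written (scores, subjects, scales).
#' @export
write_cohort <- function(table, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("scores.csv", "subjects.csv", "scales.csv"))
  scores_df <- data.frame(subject_id = rownames(table$scores),
                          table$scores, check.names = FALSE)
  utils::write.csv(scores_df, paths[1], row.names = FALSE, na = "")
  subj <- table$subjects
  subj$group <- as.character(subj$group)
  utils::write.csv(subj, paths[2], row.names = FALSE)
  utils::write.csv(table$scales, paths[3], row.names = FALSE)
  invisible(paths)
}

#' Per-scale, per-group data coverage report
#'
#' Counts non-missing observations for every scale in every group and flags
#' scales whose count in any *used* group falls below `min_n`. Correlations on
#' very small pairwise samples are unstable, so downstream network
#' construction refuses flagged scales unless explicitly overridden.
#'
#' @param table A [cohort_table()].
#' @param min_n Minimum non-missing count per scale per group (default 10).
#' @param groups Groups the threshold applies to (default all four).
#' @return A data frame with one row per scale: non-missing counts per group,
#'   overall completeness proportion, and a logical `flagged` column.
#' @export
validate_cohort <- function(table, min_n = 10, groups = GROUP_LEVELS) {
  grp <- table$subjects$group
  counts <- sapply(GROUP_LEVELS, function(g) {
    colSums(!is.na(table$scores[grp == g, , drop = FALSE]))
  })
  counts <- matrix(counts, ncol = 4, dimnames = list(table$scales$scale_id, GROUP_LEVELS))
  completeness <- rowSums(counts) / nrow(table$scores)
  flagged <- apply(counts[, groups, drop = FALSE] < min_n, 1, any)
  data.frame(
    scale_id = table$scales$scale_id,
    instrument_id = table$scales$instrument_id,
    n_case_a = counts[, "case_a"], n_case_b = counts[, "case_b"],
    n_control_a = counts[, "control_a"], n_control_b = counts[, "control_b"],
    completeness = completeness,
    flagged = flagged,
    row.names = NULL
  )
}

#' Extract the score submatrix for one group
#' @param table A [cohort_table()].
#' @param group One of `case_a`, `case_b`, `control_a`, `control_b`.
#' @return Numeric matrix (subjects of that group x scales).
#' @export
group_scores <- function(table, group) {
  group <- match.arg(group, GROUP_LEVELS)
  table$scores[table$subjects$group == group, , drop = FALSE]
}

group_ages <- function(table, group) {
  table$subjects$age[table$subjects$group == group]
}
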