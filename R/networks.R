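#' Pearson correlation network for one group
#'
#' Computes the scales-by-scales Pearson correlation matrix over subjects of
#' one group, using pairwise-complete observations by default (instrument
#' coverage differs across subjects, so pairwise deletion maximizes data use).
#' The matrix is a signed, weighted, unthresholded network: nodes are scales,
#' edges are correlations.
#'
#' @param scores A `std_scores` object or a numeric subjects x scales matrix.
#' @param min_n Minimum pairwise-complete sample size per scale pair.
#' @param use `"pairwise"` (default) or `"listwise"` deletion.
#' @param group Optional group label recorded on the result (taken from
#'   `scores` when it is a `std_scores`).
#' @return Object of class `corr_network`: list with `r` (p x p correlation
#'   matrix, unit diagonal), `n_pairs` (pairwise-complete counts),
#'   `scale_ids`, `group`.
#' @export
correlation_network <- function(scores, min_n = 10,
                                use = c("pairwise", "listwise"),
                                group = NULL) {
  use <- match.arg(use)
  if (inherits(scores, "std_scores")) {
    if (is.null(group)) group <- scores$group
    scores <- scores$values
  }
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need at least 2 scales")
  if (use == "listwise") scores <- scores[stats::complete.cases(scores), , drop = FALSE]
  obs <- !is.na(scores)
  n_pairs <- crossprod(obs)
  off <- upper.tri(n_pairs)
  if (any(n_pairs[off] < min_n)) {
    idx <- which(off & n_pairs < min_n, arr.ind = TRUE)
    pairs <- paste0(colnames(scores)[idx[, 1]], "~", colnames(scores)[idx[, 2]])
    stop("pairwise sample size below min_n (", min_n, ") for: ",
         paste(utils::head(pairs, 10), collapse = ", "),
         if (length(pairs) > 10) " ..." else "")
  }
  sds <- apply(scores, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(sds) | sds == 0)) {
    stop("zero-variance scale(s): ",
         paste(colnames(scores)[!is.finite(sds) | sds == 0], collapse = ", "))
  }
  r <- suppressWarnings(stats::cor(scores, use = "pairwise.complete.obs"))
  diag(r) <- 1
  structure(
    list(r = r, n_pairs = n_pairs, scale_ids = colnames(scores), group = group),
    class = "corr_network"
  )
}

#' Fisher-Z transform a correlation network
#'
#' Applies the variance-stabilizing transform z = atanh(r) =
#' (1/2) log((1 + r)/(1 - r)) to every off-diagonal correlation. The diagonal
#' (r = 1, infinite z) is masked as `NA` and excluded from all downstream
#' statistics.
#'
#' @param net A `corr_network`.
#' @return Object of class `z_network`: list with `z` (p x p, `NA` diagonal),
#'   `scale_ids`, `group`.
#' @export
fisher_z <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  r <- net$r
  off <- row(r) != col(r)
  if (any(abs(r[off]) >= 1)) {
    idx <- which(off & abs(r) >= 1, arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    stop("|r| = 1 (infinite Fisher Z) for pair(s): ",
         paste(paste0(net$scale_ids[idx[, 1]], "~", net$scale_ids[idx[, 2]]),
               collapse = ", "))
  }
  z <- atanh(r)
  diag(z) <- NA_real_
  structure(list(z = z, scale_ids = net$scale_ids, group = net$group),
            class = "z_network")
}

#' Delta matrix between two groups' Z-networks
#'
#' Elementwise difference `z_a - z_b` of the two Fisher-Z networks. Positive
#' cells mean the scale pair is more strongly coupled in group A, negative
#' cells more strongly coupled in group B.
#'
#' @param z_a,z_b `z_network` objects over the identical ordered scale set.
#' @return Object of class `delta_matrix`: list with `d` (p x p, `NA`
#'   diagonal), `scale_ids`, `groups`.
#' @export
delta_matrix <- function(z_a, z_b) {
  stopifnot(inherits(z_a, "z_network"), inherits(z_b, "z_network"))
  if (!identical(z_a$scale_ids, z_b$scale_ids)) {
    stop("scale sets (or their order) differ between the two networks")
  }
  structure(
    list(d = z_a$z - z_b$z, scale_ids = z_a$scale_ids,
         groups = c(z_a$group, z_b$group)),
    class = "delta_matrix"
  )
}

#' Unique-edge vector of a symmetric matrix
#'
#' Extracts the p(p-1)/2 unique off-diagonal entries in row-major
#' upper-triangle order: (1,2), (1,3), ..., (1,p), (2,3), ...
#'
#' @param net A `z_network`, `delta_matrix`, `corr_network`, or symmetric
#'   matrix with (optionally `NA`) diagonal.
#' @param tol Symmetry tolerance for raw-matrix input.
#' @return Data frame with columns `scale_i`, `scale_j`, `value`.
#' @export
upper_triangle <- function(net, tol = 1e-12) {
  if (inherits(net, "z_network")) { m <- net$z; ids <- net$scale_ids }
  else if (inherits(net, "delta_matrix")) { m <- net$d; ids <- net$scale_ids }
  else if (inherits(net, "corr_network")) { m <- net$r; ids <- net$scale_ids }
  else {
    m <- as.matrix(net)
    ids <- colnames(m)
    if (is.null(ids)) ids <- paste0("v", seq_len(ncol(m)))
  }
  if (nrow(m) != ncol(m)) stop("input must be square")
  m0 <- m; diag(m0) <- 0
  if (max(abs(m0 - t(m0)), na.rm = TRUE) > tol) {
    stop("input matrix is not symmetric within tolerance ", tol)
  }
  lo <- lower.tri(m)
  idx <- which(lo, arr.ind = TRUE)   # column-major over (j > i): row-major (i, j)
  data.frame(
    scale_i = ids[idx[, 2]],
    scale_j = ids[idx[, 1]],
    value = m[lo],
    row.names = NULL
  )
}

# Fast internal path used by the permutation engine: Pearson correlation with
# pairwise-complete observations, returning the Fisher-Z matrix with NA
# diagonal, or NULL if any pair falls below min_n (caller redraws).
cor_z_fast <- function(scores, min_n) {
  if (anyNA(scores)) {
    n_pairs <- crossprod(!is.na(scores))
    if (any(n_pairs[upper.tri(n_pairs)] < min_n)) return(NULL)
    r <- suppressWarnings(stats::cor(scores, use = "pairwise.complete.obs"))
  } else {
    if (nrow(scores) < min_n) return(NULL)
    r <- stats::cor(scores)
  }
  r[r >= 1] <- 1 - 1e-12
  r[r <= -1] <- -1 + 1e-12
  z <- atanh(r)
  diag(z) <- NA_real_
  z
}

#' Write a square matrix to CSV (scale ids as first row/column)
#' @param m Matrix with dimnames, or a network object.
#' @param path Output path. The diagonal of Z/delta matrices is written as `NA`.
#' @export
write_matrix_csv <- function(m, path) {
  if (inherits(m, "z_network")) m <- m$z
  if (inherits(m, "delta_matrix")) m <- m$d
  if (inherits(m, "corr_network")) m <- m$r
  df <- data.frame(scale_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
}

#' Read a square matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @return Numeric matrix with scale ids as dimnames.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}
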