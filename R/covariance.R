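#' Subject-by-node feature table
#'
#' Container for per-subject node measurements (e.g. Jacobian determinants
#' from tensor-based morphometry or fractional anisotropy values sampled at
#' network nodes), the raw material of structural covariance networks.
#'
#' @param values Numeric `n_subjects x q` matrix; no missing values unless
#'   `na_action = "drop"`, which removes subjects with any missing entry.
#' @param subjects Optional subject identifiers (length `n_subjects`).
#' @param node_ids Optional node identifiers (length `q`).
#' @param na_action `"error"` (default) or `"drop"`.
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(values, subjects = NULL, node_ids = NULL,
                          na_action = c("error", "drop")) {
  na_action <- match.arg(na_action)
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort_topofilt("`values` must be a numeric matrix (subjects x nodes)",
                   "topofilt_invalid_parameter")
  }
  if (anyNA(values)) {
    if (na_action == "error") {
      abort_topofilt("missing values in feature table (use na_action = 'drop')",
                     "topofilt_invalid_parameter")
    }
    drop <- apply(values, 1L, anyNA)
    warn_topofilt(sprintf("dropping %d subject(s) with missing values",
                          sum(drop)))
    values <- values[!drop, , drop = FALSE]
    if (!is.null(subjects)) subjects <- subjects[!drop]
  }
  if (is.null(subjects)) {
    subjects <- rownames(values)
    if (is.null(subjects)) subjects <- paste0("s", seq_len(nrow(values)))
  }
  if (is.null(node_ids)) {
    node_ids <- colnames(values)
    if (is.null(node_ids)) node_ids <- paste0("n", seq_len(ncol(values)))
  }
  if (length(subjects) != nrow(values) || length(node_ids) != ncol(values)) {
    abort_topofilt("identifier lengths do not match the value matrix",
                   "topofilt_invalid_parameter")
  }
  dimnames(values) <- list(subjects, node_ids)
  structure(list(values = values,
                 subjects = as.character(subjects),
                 node_ids = as.character(node_ids)),
            class = "feature_table")
}

as_feature_table <- function(x) {
  if (inherits(x, "feature_table")) return(x)
  feature_table(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("Feature table: %d subjects x %d nodes\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Structural covariance (correlation) network
#'
#' Correlates every pair of node columns across subjects and returns the
#' resulting `q x q` correlation matrix as a [weighted_network()] with zero
#' diagonal. Negative correlations are retained as-is by default and
#' participate in the filtration over the full weight range; set
#' `absolute = TRUE` to filter on correlation magnitude instead.
#'
#' @param table A [feature_table()] or numeric subjects-by-nodes matrix with
#'   at least two subjects.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param absolute Use absolute correlations as edge weights.
#' @return A `weighted_network` with entries in `[-1, 1]` off-diagonal.
#' @export
correlation_network <- function(table, method = c("pearson", "spearman"),
                                absolute = FALSE) {
  method <- match.arg(method)
  tab <- as_feature_table(table)
  v <- tab$values
  if (nrow(v) < 2L) {
    abort_topofilt("need >= 2 subjects to correlate",
                   "topofilt_insufficient_sample")
  }
  sds <- apply(v, 2L, sd)
  if (any(sds == 0)) {
    abort_topofilt(sprintf(
      "zero variance at node(s): %s",
      paste(tab$node_ids[sds == 0], collapse = ", ")),
      "topofilt_invalid_parameter")
  }
  C <- cor(v, method = method)
  C <- (C + t(C)) / 2           # guard against last-bit asymmetry
  if (absolute) C <- abs(C)
  diag(C) <- 0
  weighted_network(C, node_labels = tab$node_ids)
}

#' Leave-one-out jackknife correlation networks
#'
#' Recomputes the group-level correlation network with each subject left out
#' in turn, producing one network replicate per subject. This turns a single
#' per-group covariance network into a sample of networks suitable for the
#' group-difference tests. Deterministic: no randomness is involved.
#'
#' @inheritParams correlation_network
#' @return List of `n_subjects` [weighted_network()] objects, named by the
#'   left-out subject, in subject order.
#' @export
jackknife_networks <- function(table, method = c("pearson", "spearman"),
                               absolute = FALSE) {
  method <- match.arg(method)
  tab <- as_feature_table(table)
  n_s <- nrow(tab$values)
  if (n_s < 3L) {
    abort_topofilt("jackknife needs >= 3 subjects",
                   "topofilt_insufficient_sample")
  }
  out <- lapply(seq_len(n_s), function(i) {
    correlation_network(
      feature_table(tab$values[-i, , drop = FALSE],
                    subjects = tab$subjects[-i], node_ids = tab$node_ids),
      method = method, absolute = absolute)
  })
  names(out) <- tab$subjects
  out
}
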