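#' Topological distances between networks
#'
#' For graph filtrations the persistence diagrams are one-dimensional sorted
#' value sets, so the 2-Wasserstein distance between two diagrams reduces to
#' order statistics: match the i-th smallest birth (death) values and sum the
#' squared differences,
#' \deqn{d_0 = \sum_i (b_i^{(1)} - b_i^{(2)})^2, \qquad
#'       d_1 = \sum_i (d_i^{(1)} - d_i^{(2)})^2.}
#' These are the distances as displayed in the underlying method (sums of
#' squared differences, no square root); set `root = TRUE` for the
#' square-rooted variant if a proper metric is wanted. The inference
#' procedures in this package are monotone-invariant, so the choice does not
#' affect permutation p-values computed from either form consistently.
#'
#' Both networks must yield diagrams of equal length (same node count and,
#' for `d_1`, the same number of non-forest edges); unequal diagrams are
#' refused rather than padded.
#'
#' @param a,b [weighted_network()] objects, square matrices, or precomputed
#'   [birth_death_decompose()] results.
#' @param root Return the square root of the sum (default `FALSE`, the form
#'   used throughout the package).
#' @return Nonnegative scalar.
#' @export
#' @examples
#' tr <- matched_weight_trees(6, seed = 1)
#' wasserstein0(tr[[1]], tr[[2]])  # 0: identical sorted edge weights
wasserstein0 <- function(a, b, root = FALSE) {
  ba <- as_birth_death(a)$births
  bb <- as_birth_death(b)$births
  if (length(ba) != length(bb)) {
    abort_topofilt(sprintf(
      "birth sets have different sizes (%d vs %d); networks are incompatible",
      length(ba), length(bb)), "topofilt_incompatible")
  }
  d <- sum((ba - bb)^2)
  if (root) sqrt(d) else d
}

#' @rdname wasserstein0
#' @export
wasserstein1 <- function(a, b, root = FALSE) {
  da <- as_birth_death(a)$deaths
  db <- as_birth_death(b)$deaths
  if (length(da) != length(db)) {
    abort_topofilt(sprintf(
      "death sets have different sizes (%d vs %d); networks are incompatible",
      length(da), length(db)), "topofilt_incompatible")
  }
  if (length(da) == 0L) return(0)  # two forests: no cycles, distance 0
  d <- sum((da - db)^2)
  if (root) sqrt(d) else d
}

#' Combined 0D + 1D topological distance
#'
#' Weighted combination `w0 * d0 + w1 * d1` of the 0D and 1D Wasserstein
#' distances; equal weights `w0 = w1 = 1` by default.
#'
#' @inheritParams wasserstein0
#' @param w0,w1 Nonnegative weights for the 0D and 1D terms.
#' @param root Return `sqrt(w0 * d0 + w1 * d1)` instead.
#' @return Nonnegative scalar.
#' @export
combined_distance <- function(a, b, w0 = 1, w1 = 1, root = FALSE) {
  check_distance_weights(w0, w1)
  d <- w0 * wasserstein0(a, b) + w1 * wasserstein1(a, b)
  if (root) sqrt(d) else d
}

check_distance_weights <- function(w0, w1) {
  if (!is_scalar_number(w0) || !is_scalar_number(w1) || w0 < 0 || w1 < 0) {
    abort_topofilt("`w0` and `w1` must be single nonnegative numbers",
                   "topofilt_invalid_parameter")
  }
}

#' Elementwise Euclidean distance between weight matrices
#'
#' The baseline geometric distance: the L2 norm of the upper-triangle
#' difference of the two weight matrices. Unlike the topological distances it
#' depends on the node labelling.
#'
#' @param a,b [weighted_network()] objects or square matrices of equal size.
#' @return Nonnegative scalar.
#' @export
matrix_euclidean_distance <- function(a, b) {
  a <- as_weighted_network(a); b <- as_weighted_network(b)
  if (a$q != b$q) {
    abort_topofilt(sprintf("node counts differ (%d vs %d)", a$q, b$q),
                   "topofilt_incompatible")
  }
  ut <- upper.tri(a$weights)
  sqrt(sum((a$weights[ut] - b$weights[ut])^2))
}

#' Pairwise topological distance matrices for two groups of networks
#'
#' Computes the `(m + n) x (m + n)` matrices of 0D, 1D and combined
#' topological distances over all pairs drawn from two groups of networks
#' with a common node set. Each network is decomposed exactly once; the
#' pairwise sums of squared differences are then evaluated on the stacked
#' sorted birth and death vectors.
#'
#' @param group1,group2 Lists of [weighted_network()] objects (or matrices);
#'   sizes `m` and `n`.
#' @param w0,w1 Weights for the combined distance `D01 = w0 * D0 + w1 * D1`.
#' @param group_names Character vector of length 2 used for the labels.
#' @return Object of class `grouped_dist`: list with symmetric nonnegative
#'   matrices `D0`, `D1`, `D01`, factor `labels` (first `m` entries group 1),
#'   `m`, `n`, `w0`, `w1` and `metric = "wasserstein"`.
#' @seealso [pairwise_matrix_distances()] for the L2 baseline,
#'   [permutation_test()] / [transposition_test()] / [z_test()] for inference.
#' @export
pairwise_distances <- function(group1, group2, w0 = 1, w1 = 1,
                               group_names = c("group1", "group2")) {
  check_distance_weights(w0, w1)
  nets <- c(as_network_list(group1), as_network_list(group2))
  m <- length(group1); n <- length(group2)
  if (m < 1L || n < 1L) {
    abort_topofilt("both groups must contain at least one network",
                   "topofilt_invalid_parameter")
  }
  qs <- vapply(nets, `[[`, integer(1), "q")
  if (length(unique(qs)) != 1L) {
    abort_topofilt("networks have different node counts",
                   "topofilt_incompatible")
  }
  bds <- lapply(nets, as_birth_death)
  nb <- vapply(bds, function(x) length(x$births), integer(1))
  nd <- vapply(bds, function(x) length(x$deaths), integer(1))
  if (length(unique(nb)) != 1L || length(unique(nd)) != 1L) {
    abort_topofilt(
      "networks yield diagrams of unequal size; cannot match order statistics",
      "topofilt_incompatible")
  }
  D0 <- squared_dist(do.call(rbind, lapply(bds, `[[`, "births")),
                     length(nets))
  D1 <- squared_dist(do.call(rbind, lapply(bds, `[[`, "deaths")),
                     length(nets))
  labels <- factor(rep(group_names, c(m, n)), levels = group_names)
  new_grouped_dist(D0 = D0, D1 = D1, D01 = w0 * D0 + w1 * D1,
                   labels = labels, m = m, n = n, w0 = w0, w1 = w1,
                   metric = "wasserstein")
}

# Pairwise sum of squared row differences; rows may be zero-length.
squared_dist <- function(mat, n_rows) {
  if (is.null(mat) || ncol(mat) == 0L) {
    return(matrix(0, n_rows, n_rows))
  }
  d <- as.matrix(dist(mat))^2
  dimnames(d) <- NULL
  d
}

#' Pairwise matrix-Euclidean distances for two groups of networks
#'
#' Baseline counterpart of [pairwise_distances()]: the entrywise L2 distance
#' [matrix_euclidean_distance()] over all pairs.
#'
#' @inheritParams pairwise_distances
#' @return A `grouped_dist` whose `D01` holds the L2 distances (`D0` and `D1`
#'   are `NULL`, `metric = "euclidean"`).
#' @export
pairwise_matrix_distances <- function(group1, group2,
                                      group_names = c("group1", "group2")) {
  nets <- c(as_network_list(group1), as_network_list(group2))
  m <- length(group1); n <- length(group2)
  qs <- vapply(nets, `[[`, integer(1), "q")
  if (length(unique(qs)) != 1L) {
    abort_topofilt("networks have different node counts",
                   "topofilt_incompatible")
  }
  ut <- upper.tri(nets[[1L]]$weights)
  flat <- do.call(rbind, lapply(nets, function(x) x$weights[ut]))
  D <- as.matrix(dist(flat))
  dimnames(D) <- NULL
  labels <- factor(rep(group_names, c(m, n)), levels = group_names)
  new_grouped_dist(D0 = NULL, D1 = NULL, D01 = D, labels = labels,
                   m = m, n = n, w0 = NA_real_, w1 = NA_real_,
                   metric = "euclidean")
}

as_network_list <- function(x) {
  if (inherits(x, "weighted_network")) x <- list(x)
  lapply(x, as_weighted_network)
}

new_grouped_dist <- function(D0, D1, D01, labels, m, n, w0, w1, metric) {
  structure(list(D0 = D0, D1 = D1, D01 = D01, labels = labels,
                 m = m, n = n, w0 = w0, w1 = w1, metric = metric),
            class = "grouped_dist")
}

#' Extract one distance matrix from a `grouped_dist`
#'
#' @param x A `grouped_dist`.
#' @param which `"combined"` (`D01`), `"d0"` or `"d1"`.
#' @return Symmetric numeric matrix.
#' @export
dist_matrix <- function(x, which = c("combined", "d0", "d1")) {
  stopifnot(inherits(x, "grouped_dist"))
  which <- match.arg(which)
  out <- switch(which, combined = x$D01, d0 = x$D0, d1 = x$D1)
  if (is.null(out)) {
    abort_topofilt(sprintf("component '%s' not available for metric '%s'",
                           which, x$metric), "topofilt_invalid_parameter")
  }
  out
}

#' @export
print.grouped_dist <- function(x, ...) {
  cat(sprintf("Grouped %s distance matrix: (%d + %d) x (%d + %d)\n",
              x$metric, x$m, x$n, x$m, x$n))
  invisible(x)
}
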