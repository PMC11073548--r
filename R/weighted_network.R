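#' Weighted network
#'
#' Construct a weighted network `G = (V, w)` on `q` nodes from a symmetric
#' real-valued `q x q` weight matrix with zero diagonal. This is the substrate
#' of the graph filtration: thresholding the weights at increasing values
#' produces a nested sequence of binary graphs whose topology is summarised by
#' [birth_death_decompose()] and [betti_curves()].
#'
#' Edges with weight exactly 0 are treated as absent by default, which matches
#' count-valued connectivity data (a zero tract count is "no edge"). Supply an
#' explicit logical `mask` to override, e.g. to declare a zero-weight edge as
#' present or to drop edges with nonzero weights.
#'
#' @param weights Numeric `q x q` matrix; must be symmetric with zero diagonal
#'   and finite entries. Symmetry is required exactly unless `symmetrize` is
#'   `TRUE`, in which case asymmetries up to `tol` are averaged away with a
#'   warning (larger asymmetries are still an error).
#' @param node_labels Optional character vector of length `q`.
#' @param mask Optional logical `q x q` symmetric matrix marking which edges
#'   exist. `NULL` (default) means "an edge exists iff its weight is nonzero".
#' @param symmetrize Logical; allow near-symmetric input (see `weights`).
#' @param tol Largest absolute asymmetry repaired when `symmetrize = TRUE`.
#'
#' @return An object of class `weighted_network`: a list with elements `q`,
#'   `weights`, `node_labels` and (possibly `NULL`) `mask`.
#' @seealso [threshold_graph()], [birth_death_decompose()], [betti_curves()]
#' @export
#' @examples
#' w <- matrix(0, 3, 3)
#' w[upper.tri(w)] <- c(0.5, 0.9, 0.2)
#' net <- weighted_network(w + t(w))
#' net
weighted_network <- function(weights, node_labels = NULL, mask = NULL,
                             symmetrize = FALSE, tol = 1e-8) {
  if (!is.matrix(weights) || !is.numeric(weights)) {
    abort_topofilt("`weights` must be a numeric matrix",
                   "topofilt_invalid_parameter")
  }
  q <- nrow(weights)
  if (q < 1L || ncol(weights) != q) {
    abort_topofilt("`weights` must be a square matrix with at least one node",
                   "topofilt_invalid_parameter")
  }
  if (any(!is.finite(weights))) {
    bad <- which(!is.finite(weights), arr.ind = TRUE)[1L, ]
    abort_topofilt(
      sprintf("non-finite weight at position (%d, %d)", bad[1L], bad[2L]),
      "topofilt_invalid_parameter")
  }
  asym <- max(abs(weights - t(weights)))
  if (asym > 0) {
    if (symmetrize && asym <= tol) {
      warn_topofilt(sprintf(
        "symmetrizing weights (max asymmetry %.3g)", asym))
      weights <- (weights + t(weights)) / 2
    } else {
      abort_topofilt(sprintf(
        "weight matrix is not symmetric (max asymmetry %.3g)", asym),
        "topofilt_invalid_parameter")
    }
  }
  if (any(diag(weights) != 0)) {
    abort_topofilt("diagonal weights must be zero (no self-loops)",
                   "topofilt_invalid_parameter")
  }
  if (!is.null(node_labels)) {
    node_labels <- as.character(node_labels)
    if (length(node_labels) != q) {
      abort_topofilt("`node_labels` must have one entry per node",
                     "topofilt_invalid_parameter")
    }
  }
  if (!is.null(mask)) {
    if (!is.matrix(mask) || !is.logical(mask) ||
        !identical(dim(mask), dim(weights)) || !identical(mask, t(mask))) {
      abort_topofilt("`mask` must be a symmetric logical q x q matrix",
                     "topofilt_invalid_parameter")
    }
    diag(mask) <- FALSE
  }
  dimnames(weights) <- if (is.null(node_labels)) NULL else
    list(node_labels, node_labels)
  structure(list(q = q, weights = weights, node_labels = node_labels,
                 mask = mask),
            class = "weighted_network")
}

#' Coerce to a weighted network
#'
#' @param x A `weighted_network` or a square numeric matrix.
#' @param ... Passed on to [weighted_network()] when constructing from a matrix.
#' @return A `weighted_network`.
#' @export
as_weighted_network <- function(x, ...) {
  if (inherits(x, "weighted_network")) return(x)
  if (is.matrix(x)) return(weighted_network(x, ...))
  abort_topofilt("cannot coerce object to a weighted network",
                 "topofilt_invalid_parameter")
}

# Logical q x q matrix of present edges (diagonal always FALSE).
edge_mask <- function(net) {
  m <- if (is.null(net$mask)) net$weights != 0 else net$mask
  diag(m) <- FALSE
  m
}

# Present edges as a data.frame(i, j, w) with i < j.
edge_list <- function(net) {
  keep <- upper.tri(net$weights) & edge_mask(net)
  data.frame(i = row(net$weights)[keep],
             j = col(net$weights)[keep],
             w = net$weights[keep])
}

n_edges <- function(net) sum(edge_mask(net)) / 2

is_complete <- function(net) n_edges(net) == net$q * (net$q - 1) / 2

#' @export
print.weighted_network <- function(x, ...) {
  r <- n_edges(x)
  cat(sprintf("Weighted network: %d nodes, %d of %d possible edges\n",
              x$q, r, x$q * (x$q - 1) / 2))
  if (r > 0) {
    w <- edge_list(x)$w
    cat(sprintf("Edge weights in [%.4g, %.4g]\n", min(w), max(w)))
  }
  invisible(x)
}

#' Threshold a weighted network into a binary graph
#'
#' Returns the adjacency matrix of the binary graph `G_eps` that keeps exactly
#' the edges with weight strictly greater than `eps`. The strict inequality is
#' deliberate and bit-exact: an edge whose weight equals the threshold is
#' removed, so curves evaluated at event values (the weights themselves) sit on
#' the right-continuous side of each step.
#'
#' @param net A [weighted_network()] (or square matrix coercible to one).
#' @param eps Finite numeric threshold.
#' @return Integer 0/1 `q x q` symmetric adjacency matrix with zero diagonal.
#' @export
threshold_graph <- function(net, eps) {
  net <- as_weighted_network(net)
  if (!is_scalar_number(eps)) {
    abort_topofilt("`eps` must be a single finite number",
                   "topofilt_invalid_parameter")
  }
  adj <- (net$weights > eps) & edge_mask(net)
  storage.mode(adj) <- "integer"
  adj
}

#' Relabel the nodes of a network
#'
#' Conjugates the weight matrix (and mask) by a node permutation. Topological
#' summaries are invariant under this operation.
#'
#' @param net A `weighted_network`.
#' @param perm Integer permutation of `1:q`.
#' @return A `weighted_network` with permuted nodes.
#' @export
permute_nodes <- function(net, perm) {
  net <- as_weighted_network(net)
  if (length(perm) != net$q || !setequal(perm, seq_len(net$q))) {
    abort_topofilt("`perm` must be a permutation of 1:q",
                   "topofilt_invalid_parameter")
  }
  weighted_network(net$weights[perm, perm, drop = FALSE],
                   node_labels = net$node_labels[perm],
                   mask = if (is.null(net$mask)) NULL else
                     net$mask[perm, perm, drop = FALSE])
}
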