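#' Noisy point-cloud circle-pattern networks
#'
#' Generates groups of geometric networks with identical topology: `n_nodes`
#' points are placed at evenly spaced arc-length positions along a planar
#' circular pattern, isotropic Gaussian noise (sd `noise_sd`) is added to the
#' coordinates, and the connectivity matrix is the pairwise Euclidean
#' distance between points.
#'
#' The default pattern is a closed figure-eight of two unit circles tangent
#' at the origin. `rotation` rotates the pattern beneath a sampling anchor
#' that stays fixed in the world frame: the node at index `k` always sits at
#' the k-th arc-length position *as seen from the world frame*, so rotating
#' the pattern re-indexes the nodes cyclically while the pairwise-distance
#' distribution (rotation being an isometry) is unchanged. Consequently
#' rotated groups are exactly topologically exchangeable, while their weight
#' matrices differ entrywise whenever the rotation is not a symmetry of the
#' pattern: for the figure-eight, rotations 0 and `pi` are entrywise
#' equivalent ("horizontal") and `pi/2`, `3*pi/2` are equivalent
#' ("vertical"), so an entrywise matrix distance sees a horizontal/vertical
#' block structure that the topological distances do not.
#'
#' Because the graph filtration removes *small* weights first while raw
#' Euclidean distance has the opposite polarity (close points = strong
#' connection), the distances are converted to affinities
#' `max(d) - d` by default (`affinity = TRUE`); the farthest pair then gets
#' weight 0 and drops out as an absent edge. Set `affinity = FALSE` to keep
#' raw distances as weights.
#'
#' @param n_networks Number of networks to generate (default 5).
#' @param n_nodes Nodes per network (default 60, `>= 3`).
#' @param noise_sd Coordinate noise standard deviation (default 0.3, `>= 0`).
#' @param rotation Pattern rotation in radians (reduced modulo `2*pi`).
#' @param pattern `"two_circles"` (figure-eight, default) or `"circle"`.
#' @param affinity Convert distances to affinities (default `TRUE`).
#' @param seed Optional integer seed (`set.seed`).
#' @return List of [weighted_network()] objects; each carries its generating
#'   point coordinates in `attr(net, "coordinates")`.
#' @export
circle_pattern_networks <- function(n_networks = 5L, n_nodes = 60L,
                                    noise_sd = 0.3, rotation = 0,
                                    pattern = c("two_circles", "circle"),
                                    affinity = TRUE, seed = NULL) {
  pattern <- match.arg(pattern)
  if (!is_count(n_networks)) {
    abort_topofilt("`n_networks` must be a positive integer",
                   "topofilt_invalid_parameter")
  }
  if (!is_count(n_nodes, min = 3L)) {
    abort_topofilt("`n_nodes` must be an integer >= 3",
                   "topofilt_invalid_parameter")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    abort_topofilt("`noise_sd` must be a single nonnegative number",
                   "topofilt_invalid_parameter")
  }
  if (!is_scalar_number(rotation)) {
    abort_topofilt("`rotation` must be a single finite number",
                   "topofilt_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  rotation <- rotation %% (2 * pi)
  base <- pattern_coordinates(pattern, n_nodes, rotation)
  lapply(seq_len(n_networks), function(k) {
    coords <- base + matrix(rnorm(2L * n_nodes, sd = noise_sd), n_nodes, 2L)
    d <- as.matrix(dist(coords))
    dimnames(d) <- NULL
    w <- if (affinity) max(d) - d else d
    diag(w) <- 0
    net <- weighted_network(w)
    attr(net, "coordinates") <- coords
    net
  })
}

# Node coordinates for a rotated pattern sampled at fixed world-frame
# arc-length anchors. The parameter shift implements the re-indexing; the
# rotation matrix is applied on top so the returned cloud is visually rotated.
pattern_coordinates <- function(pattern, n_nodes, rotation) {
  R <- matrix(c(cos(rotation), sin(rotation),
                -sin(rotation), cos(rotation)), 2L, 2L)
  if (pattern == "circle") {
    s <- 2 * pi * (seq_len(n_nodes) - 1L) / n_nodes + rotation
    p <- cbind(cos(s), sin(s))
  } else {
    # figure-eight: circle A centered (1, 0) then its point reflection,
    # parameterized over [0, 4*pi); p(s + 2*pi) = -p(s).
    s <- (4 * pi * (seq_len(n_nodes) - 1L) / n_nodes + 2 * rotation) %%
      (4 * pi)
    first <- s < 2 * pi
    t <- ifelse(first, s, s - 2 * pi)
    p <- cbind(1 - cos(t), sin(t))
    p[!first, ] <- -p[!first, , drop = FALSE]
  }
  p %*% t(R)
}

#' Pair of distinct trees with identical sorted edge weights
#'
#' Builds two trees on `q` nodes with different shapes but the same multiset
#' of `q - 1` distinct edge weights. Under graph filtration both carry the
#' same birth set (all tree edges) and an empty death set, so their 0D and 1D
#' topological distances vanish even though the trees are different graphs —
#' the canonical illustration of why tree-like connectivity carries little
#' filtration-detectable signal.
#'
#' @param q Number of nodes (`>= 3`).
#' @param shape_a,shape_b Tree shapes: `"path"`, `"star"` or `"binary"`
#'   (complete binary heap order).
#' @param weights Optional ascending vector of `q - 1` distinct positive
#'   weights; drawn as sorted `runif(q - 1)` values when omitted.
#' @param seed Optional integer seed used when drawing weights.
#' @return List of two [weighted_network()] objects.
#' @export
matched_weight_trees <- function(q, shape_a = "path", shape_b = "star",
                                 weights = NULL, seed = NULL) {
  if (!is_count(q, min = 3L)) {
    abort_topofilt("`q` must be an integer >= 3",
                   "topofilt_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(weights)) {
    weights <- sort(runif(q - 1L))
    while (anyDuplicated(weights) || any(weights == 0)) {
      weights <- sort(runif(q - 1L))
    }
  }
  if (length(weights) != q - 1L || any(!is.finite(weights)) ||
      any(weights <= 0) || anyDuplicated(weights) || is.unsorted(weights)) {
    abort_topofilt(
      "`weights` must be q - 1 ascending distinct positive values",
      "topofilt_invalid_parameter")
  }
  build <- function(shape) {
    ed <- tree_edges(shape, q)
    w <- matrix(0, q, q)
    w[ed] <- weights
    weighted_network(w + t(w))
  }
  list(build(shape_a), build(shape_b))
}

tree_edges <- function(shape, q) {
  kids <- 2:q
  switch(shape,
    path = cbind(kids - 1L, kids),
    star = cbind(rep(1L, q - 1L), kids),
    binary = cbind(kids %/% 2L, kids),
    abort_topofilt(sprintf("unknown tree shape '%s'", shape),
                   "topofilt_invalid_parameter"))
}

#' Factor-model feature table with controllable inter-node correlation
#'
#' Each node value is `sqrt(rho) * f_s + sqrt(1 - rho) * e`, with a shared
#' standard-normal subject factor `f_s` and independent standard-normal
#' noise, so every pair of nodes has population correlation `rho`. Raising
#' `rho` makes the resulting covariance network denser at any correlation
#' threshold — fewer components (lower Betti-0) and more cycles (higher
#' Betti-1) — which is the mechanism the group-difference tests are meant to
#' detect.
#'
#' @param n_subjects Number of subjects (rows).
#' @param q Number of nodes (columns).
#' @param rho Target inter-node correlation in `[0, 1)`.
#' @param seed Optional integer seed.
#' @return A [feature_table()].
#' @export
factor_model_table <- function(n_subjects, q, rho, seed = NULL) {
  if (!is_count(n_subjects) || !is_count(q)) {
    abort_topofilt("`n_subjects` and `q` must be positive integers",
                   "topofilt_invalid_parameter")
  }
  if (!is_scalar_number(rho) || rho < 0 || rho >= 1) {
    abort_topofilt("`rho` must lie in [0, 1)",
                   "topofilt_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  f <- rnorm(n_subjects)
  values <- sqrt(rho) * matrix(f, n_subjects, q) +
    sqrt(1 - rho) * matrix(rnorm(n_subjects * q), n_subjects, q)
  feature_table(values)
}

#' Random complete network with distinct i.i.d. edge weights
#'
#' @param q Number of nodes (`>= 2`).
#' @param weight_distribution Function of one argument `n` returning `n`
#'   random weights (default [stats::runif]). Draws containing ties or zeros
#'   are redrawn so the network is complete with distinct weights.
#' @param seed Optional integer seed.
#' @return A [weighted_network()].
#' @export
random_complete_network <- function(q, weight_distribution = runif,
                                    seed = NULL) {
  if (!is_count(q, min = 2L)) {
    abort_topofilt("`q` must be an integer >= 2",
                   "topofilt_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- q * (q - 1L) / 2
  w <- weight_distribution(r)
  while (anyDuplicated(w) || any(w == 0) || any(!is.finite(w))) {
    w <- weight_distribution(r)
  }
  mat <- matrix(0, q, q)
  mat[upper.tri(mat)] <- w
  weighted_network(mat + t(mat))
}
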