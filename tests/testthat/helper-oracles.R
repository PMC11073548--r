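# Independent oracles used to cross-check the package implementation.
# These deliberately take different routes: igraph for components and
# spanning trees, exhaustive enumeration at tiny q, and literal nested-loop
# evaluations of the printed formulas.

# Random symmetric weight matrix with distinct positive entries (raw matrix,
# not built through package generators, for oracle-side independence).
random_weight_matrix <- function(q) {
  w <- matrix(0, q, q)
  vals <- runif(q * (q - 1) / 2)
  while (anyDuplicated(vals)) vals <- runif(q * (q - 1) / 2)
  w[upper.tri(w)] <- vals
  w + t(w)
}

# Number of connected components of the graph keeping edges with weight > eps
# (all q nodes retained), via igraph.
oracle_components <- function(w, eps) {
  keep <- which(upper.tri(w) & w > eps & w != 0, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(nrow(w))
  g <- igraph::graph_from_edgelist(keep, directed = FALSE)
  g <- igraph::add_vertices(g, nrow(w) - igraph::gorder(g))
  igraph::components(g)$no
}

# Maximum-spanning-tree edge weights via igraph (Prim on negated weights).
oracle_mst_weights <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  t <- igraph::mst(g, weights = -igraph::E(g)$weight)
  sort(igraph::E(t)$weight)
}

# Exhaustive maximum spanning tree: enumerate all (q-1)-edge subsets, keep
# spanning trees, return the sorted weights of the heaviest. Only for tiny q.
oracle_mst_weights_bruteforce <- function(w) {
  q <- nrow(w)
  idx <- which(upper.tri(w) & w != 0)
  ii <- row(w)[idx]; jj <- col(w)[idx]; ww <- w[idx]
  best <- -Inf; best_w <- NULL
  for (sel in asplit(utils::combn(length(idx), q - 1L), 2L)) {
    g <- igraph::graph_from_edgelist(cbind(ii[sel], jj[sel]),
                                     directed = FALSE)
    if (igraph::gorder(g) == q && igraph::is_connected(g)) {
      tot <- sum(ww[sel])
      if (tot > best) {
        best <- tot
        best_w <- sort(ww[sel])
      }
    }
  }
  best_w
}

# Literal nested-loop within/between sums.
oracle_within_between <- function(D, g1) {
  n <- nrow(D)
  l_W <- 0; l_B <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (g1[i] == g1[j]) l_W <- l_W + D[i, j] else l_B <- l_B + D[i, j]
    }
  }
  list(l_W = l_W, l_B = l_B)
}
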