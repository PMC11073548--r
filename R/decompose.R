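#' Birth-death decomposition of a weighted network
#'
#' Partitions the edge-weight multiset of a weighted graph into a *birth set*
#' and a *death set*. Under the graph filtration (edges with weight `> eps`
#' kept, `eps` increasing), every edge weight is an event: either a connected
#' component is born when the edge disappears (the edge belonged to a maximum
#' spanning forest) or a cycle dies (any other edge). The birth set is exactly
#' the weight multiset of a maximum spanning forest and forms the 0D
#' persistence diagram; the death set holds the remaining weights and forms
#' the 1D diagram. For a connected complete graph on `q` nodes the sets have
#' sizes `q - 1` and `(q - 1)(q - 2) / 2`.
#'
#' The forest is found with a single Kruskal pass: edges are scanned in order
#' of decreasing weight (ties broken by ascending node indices for
#' reproducibility) and accepted when they join two distinct union-find
#' components. Sorting dominates, so the runtime is `O(q^2 log q)`. When equal
#' weights make the forest non-unique, the returned *weight* partition is
#' still deterministic and the diagrams depend only on the weights.
#'
#' @param net A [weighted_network()] or square symmetric matrix.
#' @return An object of class `birth_death`: list with sorted ascending
#'   `births` and `deaths`, the corresponding `birth_edges` / `death_edges`
#'   (two-column index matrices, rows aligned with the sorted values), node
#'   count `q`, component count `n_components` of the fully weighted graph,
#'   and `weights_sorted` (all present edge weights, ascending).
#' @seealso [betti_curves()], [wasserstein0()]
#' @export
#' @examples
#' net <- random_complete_network(5, seed = 1)
#' bd <- birth_death_decompose(net)
#' length(bd$births)  # q - 1 = 4
#' length(bd$deaths)  # (q-1)(q-2)/2 = 6
birth_death_decompose <- function(net) {
  net <- as_weighted_network(net)
  q <- net$q
  el <- edge_list(net)
  n_e <- nrow(el)
  if (n_e == 0L) {
    return(new_birth_death(numeric(0), numeric(0),
                           matrix(integer(0), 0, 2), matrix(integer(0), 0, 2),
                           q = q, n_components = q))
  }
  ord <- order(-el$w, el$i, el$j)
  ei <- el$i[ord]; ej <- el$j[ord]; ew <- el$w[ord]

  parent <- seq_len(q)
  find_root <- function(x) {
    # path halving
    while (parent[x] != x) {
      parent[x] <<- parent[[parent[x]]]
      x <- parent[x]
    }
    x
  }
  is_birth <- logical(n_e)
  for (e in seq_len(n_e)) {
    ra <- find_root(ei[e])
    rb <- find_root(ej[e])
    if (ra != rb) {
      parent[ra] <- rb
      is_birth[e] <- TRUE
    }
  }
  # edges were scanned descending; report values ascending
  bsel <- rev(which(is_birth))
  dsel <- rev(which(!is_birth))
  new_birth_death(
    births = ew[bsel], deaths = ew[dsel],
    birth_edges = cbind(i = ei[bsel], j = ej[bsel]),
    death_edges = cbind(i = ei[dsel], j = ej[dsel]),
    q = q, n_components = q - sum(is_birth))
}

new_birth_death <- function(births, deaths, birth_edges, death_edges,
                            q, n_components) {
  structure(list(births = births, deaths = deaths,
                 birth_edges = birth_edges, death_edges = death_edges,
                 q = q, n_components = n_components,
                 weights_sorted = sort(c(births, deaths))),
            class = "birth_death")
}

as_birth_death <- function(x) {
  if (inherits(x, "birth_death")) return(x)
  birth_death_decompose(x)
}

#' @export
print.birth_death <- function(x, ...) {
  cat(sprintf(
    "Birth-death decomposition: %d nodes, %d components\n", x$q,
    x$n_components))
  cat(sprintf("  births (0D diagram): %d values\n", length(x$births)))
  cat(sprintf("  deaths (1D diagram): %d values\n", length(x$deaths)))
  invisible(x)
}
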