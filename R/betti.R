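#' Betti curves over a graph filtration
#'
#' Evaluates the Betti-0 (connected components) and Betti-1 (independent
#' cycles) numbers of the thresholded graph `G_eps` over a grid of filtration
#' values. Both curves come from a single birth-death decomposition rather
#' than per-threshold component counting: with sorted births `B` and deaths
#' `D`,
#' `beta0(eps) = q - #\{b in B : b > eps\}` and `beta1(eps) = #\{d in D : d > eps\}`,
#' which is the Euler-characteristic identity `beta1 = E(eps) - q + beta0`
#' with `E(eps)` the number of surviving edges. `beta0` is non-decreasing and
#' `beta1` non-increasing in `eps`.
#'
#' @param x A [weighted_network()], square matrix, or a precomputed
#'   [birth_death_decompose()] result.
#' @param thresholds Finite numeric filtration values, ascending (unsorted
#'   input is sorted with a warning).
#' @return Object of class `betti_curve`: list with `thresholds`, `beta0`,
#'   `beta1` and `q`; see [as.data.frame.betti_curve()].
#' @export
#' @examples
#' net <- random_complete_network(6, seed = 2)
#' betti_curves(net, default_threshold_grid(net, 10))
betti_curves <- function(x, thresholds) {
  bd <- as_birth_death(x)
  if (!is.numeric(thresholds) || length(thresholds) == 0L) {
    abort_topofilt("`thresholds` must be a non-empty numeric vector",
                   "topofilt_invalid_parameter")
  }
  if (any(!is.finite(thresholds))) {
    abort_topofilt("`thresholds` must be finite",
                   "topofilt_invalid_parameter")
  }
  if (is.unsorted(thresholds)) {
    warn_topofilt("`thresholds` not ascending; sorting")
    thresholds <- sort(thresholds)
  }
  m0 <- length(bd$births)
  m1 <- length(bd$deaths)
  # findInterval(t, v) = #{v <= t} for sorted v, so #{v > t} = m - that.
  beta0 <- bd$q - (m0 - findInterval(thresholds, bd$births))
  beta1 <- m1 - findInterval(thresholds, bd$deaths)
  structure(list(thresholds = thresholds,
                 beta0 = as.integer(beta0),
                 beta1 = as.integer(beta1),
                 q = bd$q),
            class = "betti_curve")
}

#' Default filtration threshold grid
#'
#' Builds the grid of filtration values at which [betti_curves()] is usually
#' evaluated. `"uniform"` mode returns `n_points` evenly spaced values over
#' `[min(w) - delta, max(w)]`, with a small margin `delta` so the first point
#' shows the full graph; `"exact"` mode returns every distinct edge weight
#' (the complete event set, at which the curves actually change).
#'
#' @param net A [weighted_network()] or square matrix.
#' @param n_points Number of grid points (`>= 2`); ignored in `"exact"` mode.
#' @param mode `"uniform"` or `"exact"`.
#' @return Ascending numeric vector.
#' @export
default_threshold_grid <- function(net, n_points = 100L,
                                   mode = c("uniform", "exact")) {
  net <- as_weighted_network(net)
  mode <- match.arg(mode)
  w <- edge_list(net)$w
  if (length(w) == 0L) {
    abort_topofilt("network has no edges; no threshold grid to build",
                   "topofilt_invalid_parameter")
  }
  if (mode == "exact") return(sort(unique(w)))
  if (!is_count(n_points, min = 2L)) {
    abort_topofilt("`n_points` must be an integer >= 2",
                   "topofilt_invalid_parameter")
  }
  lo <- min(w); hi <- max(w)
  span <- hi - lo
  if (span == 0) {
    warn_topofilt("all edge weights equal; grid degenerates to a margin below")
    span <- max(abs(hi), 1)
  }
  delta <- span * 1e-3
  seq(lo - delta, hi, length.out = n_points)
}

#' @export
#' @rdname betti_curves
#' @param row.names,optional,... Standard [as.data.frame()] arguments.
as.data.frame.betti_curve <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(threshold = x$thresholds, beta0 = x$beta0, beta1 = x$beta1,
             row.names = row.names, ...)
}

#' @export
print.betti_curve <- function(x, ...) {
  cat(sprintf("Betti curves on %d thresholds (q = %d)\n",
              length(x$thresholds), x$q))
  cat(sprintf("  beta0: %d .. %d  |  beta1: %d .. %d\n",
              x$beta0[1L], x$beta0[length(x$beta0)],
              x$beta1[1L], x$beta1[length(x$beta1)]))
  invisible(x)
}

#' Plot Betti curves
#'
#' @param x A `betti_curve`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.betti_curve <- function(x, ...) {
  graphics::matplot(x$thresholds, cbind(x$beta0, x$beta1), type = "s",
                    lty = 1, col = c("firebrick", "steelblue"),
                    xlab = expression(epsilon), ylab = "Betti number", ...)
  graphics::legend("right", legend = c(expression(beta[0]),
                                       expression(beta[1])),
                   col = c("firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
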