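#' Within- and between-group distance sums
#'
#' Given a pairwise distance matrix over two merged groups, returns the
#' within-group sum `l_W` (each unordered within-group pair counted once, both
#' groups pooled) and the between-group sum `l_B` (all `m * n` cross pairs).
#' These are the building blocks of the ratio statistic `phi = l_B / l_W`.
#'
#' @param D A [pairwise_distances()] result (its combined matrix is used) or a
#'   symmetric numeric distance matrix.
#' @param labels Group labels (two levels) for the rows of `D`; taken from the
#'   `grouped_dist` when omitted.
#' @return List with `l_W`, `l_B`, `m`, `n` and the logical group-1 indicator
#'   `g1`.
#' @export
within_between_sums <- function(D, labels = NULL) {
  di <- as_dist_input(D, labels)
  g1 <- di$g1
  list(l_W = sum(di$D[g1, g1]) / 2 + sum(di$D[!g1, !g1]) / 2,
       l_B = sum(di$D[g1, !g1]),
       m = sum(g1), n = sum(!g1), g1 = g1)
}

# Normalize (D, labels) input: accepts grouped_dist or matrix + labels.
as_dist_input <- function(D, labels = NULL) {
  if (inherits(D, "grouped_dist")) {
    if (is.null(labels)) labels <- D$labels
    D <- dist_matrix(D, "combined")
  }
  if (!is.matrix(D) || !is.numeric(D) || nrow(D) != ncol(D)) {
    abort_topofilt("`D` must be a square numeric distance matrix",
                   "topofilt_invalid_parameter")
  }
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    abort_topofilt("`D` must be symmetric", "topofilt_invalid_parameter")
  }
  labels <- as.factor(labels)
  if (length(labels) != nrow(D)) {
    abort_topofilt("`labels` must have one entry per row of `D`",
                   "topofilt_invalid_parameter")
  }
  if (nlevels(droplevels(labels)) != 2L) {
    abort_topofilt("exactly two groups are required",
                   "topofilt_invalid_parameter")
  }
  labels <- droplevels(labels)
  list(D = D, labels = labels, g1 = labels == levels(labels)[1L])
}

#' Ratio statistic between between- and within-group distances
#'
#' `phi = l_B / l_W`. Large values indicate that cross-group distances
#' dominate within-group distances, i.e. a topological group difference.
#' Requires at least two members per group (otherwise there are no within
#' pairs) and a strictly positive within sum.
#'
#' @inheritParams within_between_sums
#' @return Positive scalar.
#' @seealso [permutation_test()], [transposition_test()]
#' @export
ratio_statistic <- function(D, labels = NULL) {
  s <- within_between_sums(D, labels)
  if (s$m < 2L || s$n < 2L) {
    abort_topofilt("each group needs >= 2 members for the ratio statistic",
                   "topofilt_degenerate")
  }
  if (s$l_W <= 0) {
    abort_topofilt("within-group distance sum is zero; ratio undefined",
                   "topofilt_degenerate")
  }
  s$l_B / s$l_W
}

#' Permutation test on the ratio statistic
#'
#' Approximates the null distribution of `phi = l_B / l_W` by shuffling the
#' group labels of the fixed pairwise distance matrix; distances are never
#' recomputed. The p-value uses the add-one rule for the one-sided upper tail,
#' `p = (1 + #\{phi_null >= phi_obs\}) / (1 + n_perms)`, so it is never zero.
#'
#' @inheritParams within_between_sums
#' @param n_perms Number of label permutations (`>= 1`).
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called so
#'   the resampling stream is reproducible. Recorded in the report.
#' @return Object of class `topo_ratio_test`: `statistic` (observed phi),
#'   `null_values`, `p_value`, `method`, `n_resamples`, `seed`, `m`, `n`.
#' @export
permutation_test <- function(D, labels = NULL, n_perms = 2000L, seed = NULL) {
  if (!is_count(n_perms)) {
    abort_topofilt("`n_perms` must be a positive integer",
                   "topofilt_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  di <- as_dist_input(D, labels)
  obs <- ratio_statistic(di$D, di$labels)
  N <- nrow(di$D)
  m <- sum(di$g1)
  rs <- rowSums(di$D)
  S <- sum(rs) / 2                      # total over unordered pairs
  null_values <- numeric(n_perms)
  for (k in seq_len(n_perms)) {
    idx <- sample.int(N, m)
    l_B <- sum(rs[idx]) - sum(di$D[idx, idx])
    null_values[k] <- l_B / (S - l_B)
  }
  new_ratio_test(method = "permutation", statistic = obs,
                 null_values = null_values,
                 n_resamples = as.integer(n_perms),
                 full_perm_interval = NA_integer_, seed = seed,
                 m = m, n = N - m)
}

#' Online transposition test on the ratio statistic
#'
#' Scalable variant of [permutation_test()]: each resampling step swaps one
#' index from each group (a transposition) and updates `l_W` and `l_B`
#' incrementally. The update touches only the two swapped rows of the
#' distance matrix, so each step costs `O(m + n)` instead of the
#' `O((m + n)^2)` of a full relabelling. To avoid the random walk getting
#' trapped, a full random relabelling (with full recomputation) replaces the
#' state every `full_perm_interval` steps. The null trace collects phi after
#' every step; the p-value uses the same add-one upper-tail rule as the
#' permutation test.
#'
#' @inheritParams permutation_test
#' @param n_transpositions Number of sequential steps (`>= 1`).
#' @param full_perm_interval Intersperse a full permutation every this many
#'   steps (default 1000); `Inf` disables the refresh.
#' @param keep_state Also return the per-step `l_W`/`l_B` values and label
#'   indicators (used for verification; memory grows with the trace).
#' @return A `topo_ratio_test` (see [permutation_test()]); when `keep_state`
#'   is `TRUE` it has an extra element `trace` with `l_W`, `l_B` and the
#'   step-by-step group-1 indicator matrix.
#' @export
transposition_test <- function(D, labels = NULL, n_transpositions = 10000L,
                               full_perm_interval = 1000L, seed = NULL,
                               keep_state = FALSE) {
  if (!is_count(n_transpositions)) {
    abort_topofilt("`n_transpositions` must be a positive integer",
                   "topofilt_invalid_parameter")
  }
  if (!(is_count(full_perm_interval) || identical(full_perm_interval, Inf))) {
    abort_topofilt("`full_perm_interval` must be a positive integer or Inf",
                   "topofilt_invalid_parameter")
  }
  if (!is.null(seed)) set.seed(seed)
  di <- as_dist_input(D, labels)
  obs <- ratio_statistic(di$D, di$labels)
  Dm <- di$D
  N <- nrow(Dm)
  m <- sum(di$g1)
  rs <- rowSums(Dm)
  S <- sum(rs) / 2
  g <- di$g1
  l_B <- sum(Dm[g, !g])
  l_W <- S - l_B
  null_values <- numeric(n_transpositions)
  if (keep_state) {
    tr_lW <- numeric(n_transpositions)
    tr_lB <- numeric(n_transpositions)
    tr_g <- matrix(NA, N, n_transpositions)
  }
  for (k in seq_len(n_transpositions)) {
    if (is.finite(full_perm_interval) && k %% full_perm_interval == 0L) {
      idx <- sample.int(N, m)
      g <- logical(N); g[idx] <- TRUE
      l_B <- sum(rs[idx]) - sum(Dm[idx, idx])
      l_W <- S - l_B
    } else {
      in1 <- which(g); in2 <- which(!g)
      a <- in1[sample.int(m, 1L)]
      b <- in2[sample.int(N - m, 1L)]
      Da <- Dm[a, ]; Db <- Dm[b, ]
      d_W <- (sum(Da[!g]) - Da[b] - sum(Da[g])) +
             (sum(Db[g]) - Db[a] - sum(Db[!g]))
      l_W <- l_W + d_W
      l_B <- l_B - d_W
      g[a] <- FALSE; g[b] <- TRUE
    }
    null_values[k] <- l_B / l_W
    if (keep_state) {
      tr_lW[k] <- l_W; tr_lB[k] <- l_B; tr_g[, k] <- g
    }
  }
  out <- new_ratio_test(method = "transposition", statistic = obs,
                        null_values = null_values,
                        n_resamples = as.integer(n_transpositions),
                        full_perm_interval =
                          if (is.finite(full_perm_interval))
                            as.integer(full_perm_interval) else NA_integer_,
                        seed = seed, m = m, n = N - m)
  if (keep_state) out$trace <- list(l_W = tr_lW, l_B = tr_lB, g1 = tr_g)
  out
}

new_ratio_test <- function(method, statistic, null_values, n_resamples,
                           full_perm_interval, seed, m, n) {
  structure(list(method = method,
                 statistic = statistic,
                 null_values = null_values,
                 p_value = (1 + sum(null_values >= statistic)) /
                   (1 + length(null_values)),
                 n_resamples = n_resamples,
                 full_perm_interval = full_perm_interval,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 m = m, n = n),
            class = "topo_ratio_test")
}

#' @export
print.topo_ratio_test <- function(x, ...) {
  cat(sprintf("Topological ratio test (%s, %d resamples)\n",
              x$method, x$n_resamples))
  cat(sprintf("  groups: m = %d, n = %d\n", x$m, x$n))
  cat(sprintf("  phi = %.6g,  p = %.6g (one-sided, add-one rule)\n",
              x$statistic, x$p_value))
  invisible(x)
}
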