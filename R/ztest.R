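#' Parametric Z-test on between- versus within-group distances
#'
#' Treats the pairwise within-group distance `L_W` and between-group distance
#' `L_B` as random variables and compares their means. Moments are computed
#' over *ordered* pairs, i.e. with denominators `m(m-1) + n(n-1)` (within,
#' both groups pooled) and `m * n` (between); because the distance matrix is
#' symmetric this equals the mean over distinct pairs. Variances are the
#' second moment minus the squared mean, clipped at zero with a warning if
#' floating-point cancellation drives them negative. The statistic is
#' \deqn{Z = \frac{\bar L_B - \bar L_W}
#'   {\sqrt{V L_B / (mn) + V L_W / (m(m-1) + n(n-1))}}}
#' tested one-sided against the upper tail of N(0, 1), matching the
#' alternative that between-group distances exceed within-group distances.
#'
#' @inheritParams within_between_sums
#' @return Object of class `topo_z_test`: `mean_within`, `mean_between`,
#'   `var_within`, `var_between`, `z`, `p_value`, `m`, `n`.
#' @seealso [ks_normality_check()] to probe the normality of simulated null
#'   Z values.
#' @export
z_test <- function(D, labels = NULL) {
  di <- as_dist_input(D, labels)
  g1 <- di$g1
  m <- sum(g1); n <- sum(!g1)
  if (m < 2L || n < 2L) {
    abort_topofilt("each group needs >= 2 members for the Z-test",
                   "topofilt_degenerate")
  }
  W1 <- di$D[g1, g1]; W2 <- di$D[!g1, !g1]; B <- di$D[g1, !g1]
  if (all(di$D == 0)) {
    abort_topofilt("all distances are zero; Z-test undefined",
                   "topofilt_degenerate")
  }
  n_w <- m * (m - 1) + n * (n - 1)          # ordered within pairs
  mean_w <- (sum(W1) + sum(W2)) / n_w       # symmetric matrix: ordered sums
  mom2_w <- (sum(W1^2) + sum(W2^2)) / n_w
  mean_b <- sum(B) / (m * n)
  mom2_b <- sum(B^2) / (m * n)
  var_w <- clip_variance(mom2_w - mean_w^2, "within")
  var_b <- clip_variance(mom2_b - mean_b^2, "between")
  se2 <- var_b / (m * n) + var_w / n_w
  if (se2 <= 0) {
    abort_topofilt("pooled variance is zero; Z-test undefined",
                   "topofilt_degenerate")
  }
  z <- (mean_b - mean_w) / sqrt(se2)
  structure(list(mean_within = mean_w, mean_between = mean_b,
                 var_within = var_w, var_between = var_b,
                 z = z, p_value = pnorm(z, lower.tail = FALSE),
                 m = m, n = n),
            class = "topo_z_test")
}

clip_variance <- function(v, what) {
  if (v < 0) {
    warn_topofilt(sprintf(
      "%s-group variance %.3g negative by rounding; clipped to 0", what, v))
    v <- 0
  }
  v
}

#' @export
print.topo_z_test <- function(x, ...) {
  cat(sprintf("Z-test on between- vs within-group distances (m = %d, n = %d)\n",
              x$m, x$n))
  cat(sprintf("  mean within = %.6g, mean between = %.6g\n",
              x$mean_within, x$mean_between))
  cat(sprintf("  Z = %.6g,  one-sided p = %.6g\n", x$z, x$p_value))
  invisible(x)
}

#' Kolmogorov-Smirnov check of Z-statistic normality
#'
#' One-sample KS test of a vector of simulated Z values against the standard
#' normal, used to probe the asymptotic N(0, 1) behaviour of [z_test()] under
#' an exchangeable null.
#'
#' @param z_samples Numeric vector of at least 10 values.
#' @return List with `ks_statistic` and `p_value`.
#' @export
ks_normality_check <- function(z_samples) {
  if (!is.numeric(z_samples) || length(z_samples) < 10L ||
      any(!is.finite(z_samples))) {
    abort_topofilt("`z_samples` must be >= 10 finite numeric values",
                   "topofilt_invalid_parameter")
  }
  kt <- ks.test(z_samples, "pnorm")
  list(ks_statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}
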