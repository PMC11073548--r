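labels_mn <- function(m, n) rep(c("a", "b"), c(m, n))

# Exchangeable distance matrix with no group structure.
null_distance_matrix <- function(N) {
  D <- matrix(0, N, N)
  D[upper.tri(D)] <- runif(N * (N - 1) / 2)
  D + t(D)
}

# Distances small within groups, large between: clear topological difference.
block_distance_matrix <- function(m, n, gap = 5) {
  N <- m + n
  D <- null_distance_matrix(N)
  D[1:m, (m + 1):N] <- D[1:m, (m + 1):N] + gap
  D[(m + 1):N, 1:m] <- t(D[1:m, (m + 1):N])
  D
}

test_that("within/between sums count each unordered pair once", {
  D <- matrix(1, 4, 4); diag(D) <- 0
  s <- within_between_sums(D, labels_mn(2, 2))
  expect_identical(s$l_W, 2)
  expect_identical(s$l_B, 4)
  expect_identical(ratio_statistic(D, labels_mn(2, 2)), 2)

  set.seed(201)
  D6 <- null_distance_matrix(6)
  g1 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  lab <- ifelse(g1, "a", "b")
  o <- oracle_within_between(D6, g1)
  s6 <- within_between_sums(D6, lab)
  expect_equal(s6$l_W, o$l_W)
  expect_equal(s6$l_B, o$l_B)

  # phi is invariant to relabeling within groups
  perm <- c(2, 4, 1, 6, 3, 5)   # preserves the partition {1,2,4} / {3,5,6}
  expect_equal(ratio_statistic(D6[perm, perm], lab[perm]),
               ratio_statistic(D6, lab))
})

test_that("degenerate groupings and zero distances are refused", {
  D <- matrix(0, 4, 4)
  expect_error(ratio_statistic(D, labels_mn(2, 2)),
               class = "topofilt_degenerate")
  set.seed(211)
  D5 <- null_distance_matrix(5)
  expect_error(ratio_statistic(D5, labels_mn(1, 4)),
               class = "topofilt_degenerate")
  expect_error(within_between_sums(D5, rep("a", 5)),
               class = "topofilt_invalid_parameter")
  expect_error(within_between_sums(D5[1:4, 1:4], labels_mn(2, 2)[1:3]),
               class = "topofilt_invalid_parameter")
})

test_that("permutation test: add-one tail rule, reproducibility, power and size", {
  set.seed(221)
  D <- block_distance_matrix(5, 5, gap = 50)
  r1 <- permutation_test(D, labels_mn(5, 5), n_perms = 999, seed = 42)
  r2 <- permutation_test(D, labels_mn(5, 5), n_perms = 999, seed = 42)
  expect_identical(r1$null_values, r2$null_values)   # seeded reproducibility
  expect_identical(r1$p_value,
                   (1 + sum(r1$null_values >= r1$statistic)) / 1000)
  expect_gte(r1$p_value, 1 / 1000)                   # never zero
  expect_lt(r1$p_value, 0.05)                        # strong block structure

  # two-scale groups, the stated power case
  set.seed(222)
  Dp <- block_distance_matrix(10, 10, gap = 10)
  expect_lt(permutation_test(Dp, labels_mn(10, 10), n_perms = 2000,
                             seed = 1)$p_value, 0.01)

  # null p-values are roughly uniform (coarse check; full calibration is a
  # separate long-running acceptance simulation)
  set.seed(223)
  ps <- replicate(60, {
    permutation_test(null_distance_matrix(12), labels_mn(6, 6),
                     n_perms = 200)$p_value
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps <= 0.05), 0.2)
})

test_that("transposition updates agree with from-scratch recomputation", {
  set.seed(231)
  D <- null_distance_matrix(12)
  lab <- labels_mn(5, 7)
  tt <- transposition_test(D, lab, n_transpositions = 1000,
                           full_perm_interval = 100, seed = 9,
                           keep_state = TRUE)
  for (k in seq(1, 1000, by = 7)) {
    g <- tt$trace$g1[, k]
    l_B <- sum(D[g, !g])
    l_W <- sum(D[g, g]) / 2 + sum(D[!g, !g]) / 2
    expect_equal(tt$trace$l_B[k], l_B, tolerance = 1e-10)
    expect_equal(tt$trace$l_W[k], l_W, tolerance = 1e-10)
    expect_equal(tt$null_values[k], l_B / l_W, tolerance = 1e-10)
  }
  # group sizes are preserved at every step
  expect_true(all(colSums(tt$trace$g1) == 5))
})

test_that("a transposition followed by its inverse restores (l_W, l_B)", {
  set.seed(241)
  D <- null_distance_matrix(10)
  g <- rep(c(TRUE, FALSE), each = 5)
  l_B0 <- sum(D[g, !g])
  l_W0 <- sum(D[g, g]) / 2 + sum(D[!g, !g]) / 2
  swap_delta <- function(g, a, b) {
    (sum(D[a, !g]) - D[a, b] - sum(D[a, g])) +
      (sum(D[b, g]) - D[b, a] - sum(D[b, !g]))
  }
  d1 <- swap_delta(g, 2, 8)
  g2 <- g; g2[2] <- FALSE; g2[8] <- TRUE
  d2 <- swap_delta(g2, 8, 2)   # inverse swap
  expect_equal(l_W0 + d1 + d2, l_W0, tolerance = 1e-10)
  expect_equal(l_B0 - d1 - d2, l_B0, tolerance = 1e-10)
})

test_that("transposition and permutation nulls give consistent p-values", {
  set.seed(251)
  D <- block_distance_matrix(8, 8, gap = 0.35)   # moderate signal
  lab <- labels_mn(8, 8)
  p_perm <- permutation_test(D, lab, n_perms = 4000, seed = 3)$p_value
  p_tran <- transposition_test(D, lab, n_transpositions = 4000,
                               full_perm_interval = 100, seed = 3)$p_value
  expect_lt(abs(p_perm - p_tran),
            3 * sqrt(2 * p_perm * (1 - p_perm) / 4000) + 0.02)
})

test_that("Z-test reproduces a hand-computed case and behaves monotonically", {
  # m = n = 2; within distances 1 (pair 1-2) and 2 (pair 3-4); between
  # distances 3, 4, 5, 6. Ordered-pair moments:
  #   mean_W = (2*1 + 2*2)/4 = 1.5,  E[W^2] = (2*1 + 2*4)/4 = 2.5, V_W = 0.25
  #   mean_B = 18/4 = 4.5,  E[B^2] = 86/4 = 21.5,  V_B = 1.25
  #   Z = (4.5 - 1.5)/sqrt(1.25/4 + 0.25/4) = sqrt(24)
  D <- matrix(0, 4, 4)
  D[1, 2] <- 1; D[3, 4] <- 2
  D[1, 3] <- 3; D[1, 4] <- 4; D[2, 3] <- 5; D[2, 4] <- 6
  D <- D + t(D)
  zt <- z_test(D, labels_mn(2, 2))
  expect_equal(zt$mean_within, 1.5)
  expect_equal(zt$mean_between, 4.5)
  expect_equal(zt$var_within, 0.25)
  expect_equal(zt$var_between, 1.25)
  expect_equal(zt$z, sqrt(24))
  expect_equal(zt$p_value, pnorm(sqrt(24), lower.tail = FALSE))

  # shifting all between distances up strictly increases Z
  zs <- vapply(c(0, 0.5, 1, 2), function(s) {
    Ds <- D
    Ds[1:2, 3:4] <- Ds[1:2, 3:4] + s
    Ds[3:4, 1:2] <- t(Ds[1:2, 3:4])
    z_test(Ds, labels_mn(2, 2))$z
  }, 0)
  expect_true(all(diff(zs) > 0))

  expect_error(z_test(matrix(0, 4, 4), labels_mn(2, 2)),
               class = "topofilt_degenerate")
  set.seed(261)
  expect_error(z_test(null_distance_matrix(5), labels_mn(1, 4)),
               class = "topofilt_degenerate")
})

test_that("Z is centred near zero under an exchangeable null", {
  set.seed(271)
  zs <- replicate(1000, z_test(null_distance_matrix(30), labels_mn(15, 15))$z)
  expect_lt(abs(mean(zs)), 0.1)
})

test_that("KS normality check calibrates and detects", {
  set.seed(281)
  ok <- ks_normality_check(rnorm(1000))
  expect_gt(ok$p_value, 0.01)
  shifted <- ks_normality_check(rnorm(1000, mean = 2))
  expect_lt(shifted$p_value, 0.001)
  suppressWarnings(const <- ks_normality_check(rep(1.3, 50)))
  expect_gte(const$ks_statistic, 0.5)
  expect_error(ks_normality_check(rnorm(5)),
               class = "topofilt_invalid_parameter")
})
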