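test_that("constructor enforces symmetry, finiteness and zero diagonal", {
  w <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_s3_class(weighted_network(w), "weighted_network")

  w_asym <- w; w_asym[1, 2] <- 1 + 1e-12
  expect_error(weighted_network(w_asym), class = "topofilt_invalid_parameter")
  expect_warning(net <- weighted_network(w_asym, symmetrize = TRUE),
                 class = "topofilt_warning")
  expect_identical(net$weights, t(net$weights))
  expect_error(weighted_network(w_asym, symmetrize = TRUE, tol = 1e-15),
               class = "topofilt_invalid_parameter")

  w_na <- w; w_na[1, 2] <- w_na[2, 1] <- NaN
  expect_error(weighted_network(w_na), class = "topofilt_invalid_parameter")
  w_diag <- w; diag(w_diag) <- 1
  expect_error(weighted_network(w_diag), class = "topofilt_invalid_parameter")
  expect_error(weighted_network(w, node_labels = "a"),
               class = "topofilt_invalid_parameter")
  expect_error(weighted_network(matrix(1:4, 2, 2)),
               class = "topofilt_invalid_parameter")
})

test_that("thresholding keeps edges with weight strictly above eps", {
  w <- matrix(c(0, 0.7, 0.7, 0), 2, 2)
  net <- weighted_network(w)
  expect_identical(sum(threshold_graph(net, 0.7)), 0L)        # boundary: gone
  expect_identical(sum(threshold_graph(net, 0.7 - 1e-12)), 2L)
  expect_error(threshold_graph(net, NA_real_),
               class = "topofilt_invalid_parameter")

  # below the minimum weight the full graph survives
  set.seed(11)
  wq <- random_weight_matrix(5)
  adj <- threshold_graph(weighted_network(wq), min(wq[wq > 0]) - 1)
  expect_identical(sum(adj), 20L)
})

test_that("with distinct weights each event threshold removes one edge", {
  set.seed(21)
  w <- random_weight_matrix(4)
  net <- weighted_network(w)
  evts <- sort(w[upper.tri(w)])
  edges_left <- vapply(evts, function(e) sum(threshold_graph(net, e)) / 2, 0)
  expect_identical(edges_left, as.numeric(6 - seq_along(evts)))
})

test_that("decomposition partitions the edge-weight multiset with the stated cardinalities", {
  set.seed(31)
  for (rep in 1:25) {
    q <- sample(4:12, 1L)
    w <- random_weight_matrix(q)
    bd <- birth_death_decompose(w)
    expect_length(bd$births, q - 1L)
    expect_length(bd$deaths, (q - 1L) * (q - 2L) / 2L)
    expect_identical(sort(c(bd$births, bd$deaths)), sort(w[upper.tri(w)]))
    expect_false(is.unsorted(bd$births))
    expect_false(is.unsorted(bd$deaths))
  }
  # single-edge network
  bd2 <- birth_death_decompose(matrix(c(0, 0.7, 0.7, 0), 2, 2))
  expect_identical(bd2$births, 0.7)
  expect_length(bd2$deaths, 0L)
})

test_that("birth set is the maximum spanning tree (enumeration and igraph oracles)", {
  set.seed(41)
  for (rep in 1:8) {
    w <- random_weight_matrix(6)
    expect_equal(birth_death_decompose(w)$births,
                 oracle_mst_weights_bruteforce(w))
  }
  for (rep in 1:50) {
    q <- sample(4:8, 1L)
    w <- random_weight_matrix(q)
    expect_equal(birth_death_decompose(w)$births, oracle_mst_weights(w))
  }
})

test_that("decomposition handles disconnected and masked inputs", {
  # two 3-node cliques, no cross edges (weight 0 = absent)
  set.seed(46)
  w <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    w[p[1], p[2]] <- w[p[2], p[1]] <- runif(1)
  }
  bd <- birth_death_decompose(w)
  expect_identical(bd$n_components, 2L)
  expect_length(bd$births, 4L)                  # q - c = 6 - 2
  expect_length(bd$deaths, 2L)                  # remaining edges
  expect_identical(sort(c(bd$births, bd$deaths)), sort(w[upper.tri(w) & w != 0]))

  # explicit mask overrides the zero convention
  set.seed(51)
  wf <- random_weight_matrix(5)
  mask <- matrix(TRUE, 5, 5); mask[1, 2] <- mask[2, 1] <- FALSE
  bdm <- birth_death_decompose(weighted_network(wf, mask = mask))
  expect_length(c(bdm$births, bdm$deaths), 9L)
})

test_that("relabeling nodes leaves births, deaths and Betti curves unchanged", {
  set.seed(61)
  w <- random_weight_matrix(9)
  net <- weighted_network(w)
  perm <- sample(9)
  net_p <- permute_nodes(net, perm)
  bd <- birth_death_decompose(net)
  bd_p <- birth_death_decompose(net_p)
  expect_identical(bd$births, bd_p$births)
  expect_identical(bd$deaths, bd_p$deaths)
  grid <- default_threshold_grid(net, 25)
  expect_identical(betti_curves(net, grid)$beta0,
                   betti_curves(net_p, grid)$beta0)
  expect_identical(betti_curves(net, grid)$beta1,
                   betti_curves(net_p, grid)$beta1)
})

test_that("Betti curves match component counting and the Euler identity", {
  set.seed(71)
  for (rep in 1:20) {
    q <- sample(4:12, 1L)
    w <- random_weight_matrix(q)
    net <- weighted_network(w)
    eps <- c(min(w[w > 0]) - 0.1, default_threshold_grid(net, 10),
             sort(w[upper.tri(w)]))
    eps <- sort(eps)
    bc <- betti_curves(net, eps)
    b0_oracle <- vapply(eps, function(e) oracle_components(w, e), 0)
    expect_identical(as.numeric(bc$beta0), b0_oracle)
    E <- vapply(eps, function(e) sum(threshold_graph(net, e)) / 2, 0)
    expect_identical(as.numeric(bc$beta0 - bc$beta1), q - E)
    expect_false(is.unsorted(bc$beta0))             # beta0 non-decreasing
    expect_false(is.unsorted(rev(bc$beta1)))        # beta1 non-increasing
  }
})

test_that("Betti curves hit the full-graph and empty-graph limits", {
  set.seed(81)
  q <- 7
  w <- random_weight_matrix(q)
  bc <- betti_curves(w, c(min(w[w > 0]) - 1, max(w)))
  expect_identical(bc$beta0, c(1L, as.integer(q)))
  expect_identical(bc$beta1, c(as.integer((q - 1) * (q - 2) / 2), 0L))
  expect_error(betti_curves(w, numeric(0)),
               class = "topofilt_invalid_parameter")
  expect_warning(bc2 <- betti_curves(w, c(0.5, 0.1)),
                 class = "topofilt_warning")
  expect_identical(bc2$thresholds, c(0.1, 0.5))
})

test_that("threshold grids cover the weight range; exact mode is the event set", {
  set.seed(91)
  w <- random_weight_matrix(4)
  net <- weighted_network(w)
  g <- default_threshold_grid(net, 5)
  expect_length(g, 5L)
  expect_lt(g[1], min(w[w > 0]))
  expect_identical(g[5], max(w))
  expect_length(default_threshold_grid(net, mode = "exact"), 6L)

  # exact-mode curves agree with a dense grid wherever thresholds coincide
  ex <- default_threshold_grid(net, mode = "exact")
  dense <- sort(unique(c(ex, default_threshold_grid(net, 200))))
  bc_d <- betti_curves(net, dense)
  bc_e <- betti_curves(net, ex)
  at <- match(ex, dense)
  expect_identical(bc_d$beta0[at], bc_e$beta0)
  expect_identical(bc_d$beta1[at], bc_e$beta1)

  expect_error(default_threshold_grid(net, 1),
               class = "topofilt_invalid_parameter")
  w_const <- matrix(0.5, 3, 3); diag(w_const) <- 0
  expect_warning(default_threshold_grid(weighted_network(w_const), 4),
                 class = "topofilt_warning")
})
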