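test_that("both null constructions conserve nodes, edges, and the weight multiset", {
  set.seed(31)
  for (rep in 1:6) {
    net <- rand_net(15, p = 0.3)
    for (null in list(lattice_null(net, seed = rep),
                      random_null(net, seed = rep))) {
      expect_identical(null$n_nodes, net$n_nodes)
      expect_identical(sorted_weights(null), sorted_weights(net))
    }
    expect_equal(sum(lattice_null(net, seed = rep)$weights),
                 sum(net$weights), tolerance = 1e-15)
  }
})

test_that("the lattice null fills shells strongest-first", {
  # 6 nodes, 6 edges: the distance-1 shell has exactly 6 slots, so every
  # weight must land at ring distance 1
  m <- matrix(0, 6, 6)
  pairs <- cbind(c(1, 1, 2, 2, 3, 4), c(4, 3, 5, 6, 6, 6))
  for (k in 1:6) m[pairs[k, 1], pairs[k, 2]] <- m[pairs[k, 2], pairs[k, 1]] <- k
  latt <- lattice_null(make_network(m), seed = 2)
  ring_d <- abs(outer(1:6, 1:6, "-"))
  ring_d <- pmin(ring_d, 6 - ring_d)
  expect_true(all(ring_d[latt$weights > 0] == 1))
  expect_identical(sorted_weights(latt), as.numeric(1:6))

  # a weighted ring lattice is a fixed point up to within-shell shuffling:
  # the weight multiset found at each ring distance is reproduced exactly
  wl <- weighted_ring_lattice(30, 4)
  latt2 <- lattice_null(wl, seed = 9)
  for (d in 1:4) {
    expect_identical(sort(latt2$weights[ring_distance_at(30, d)]),
                     sort(wl$weights[ring_distance_at(30, d)]))
  }
  expect_true(all(latt2$weights[!ring_distance_at(30, 4, within = TRUE)] == 0))
})

test_that("lattice null is deterministic given the seed", {
  set.seed(8)
  net <- rand_net(20, p = 0.3)
  expect_identical(lattice_null(net, seed = 123)$weights,
                   lattice_null(net, seed = 123)$weights)
  expect_identical(random_null(net, seed = 5)$weights,
                   random_null(net, seed = 5)$weights)
})

test_that("lattice nulls cluster more and stretch paths relative to random nulls", {
  set.seed(77)
  net <- rand_net(40, p = 0.3)
  cw <- function(x) clustering_coefficient(x, "onnela")
  lw <- function(x) char_path_length(x, weighted = TRUE)$char_path_length
  stats <- vapply(1:10, function(k) {
    latt <- lattice_null(net, seed = 300 + k)
    rand <- random_null(net, seed = 600 + k)
    c(cw(latt), cw(rand), lw(latt), lw(rand))
  }, numeric(4))
  expect_gt(mean(stats[1, ]), mean(stats[2, ]))  # C_latt > C_rand
  expect_gt(mean(stats[3, ]), mean(stats[4, ]))  # L_latt > L_rand
})

test_that("the random null spreads degrees uniformly", {
  set.seed(14)
  net <- rand_net(20, p = 0.2)
  deg <- numeric(20)
  for (k in 1:100) {
    rn <- random_null(net, seed = 1000 + k)
    deg <- deg + rowSums(rn$weights > 0)
  }
  expect_gt(stats::chisq.test(deg)$p.value, 0.01)
})

test_that("degree-preserving null keeps the degree sequence exactly and rejects weights", {
  set.seed(19)
  net <- rand_net(30, p = 0.2, weighted = FALSE)
  dp <- degree_preserving_null(net, seed = 4)
  expect_identical(sort(rowSums(dp$weights)), sort(rowSums(net$weights)))
  expect_true(dp$is_binary)

  wnet <- rand_net(10, p = 0.5, weighted = TRUE)
  expect_error(degree_preserving_null(wnet), "binary")

  # randomized lattice approaches random-graph statistics
  rl <- ring_lattice(500, 5)
  dp2 <- degree_preserving_null(rl, seed = 21)
  expect_lt(clustering_coefficient(dp2, "binary"), 0.1)
  expect_lt(char_path_length(dp2, weighted = FALSE)$char_path_length, 5)
})

test_that("null_reference_stats orients the deviations correctly at the endpoints", {
  wl <- weighted_ring_lattice(80, 4)
  ns <- null_reference_stats(wl, n_realizations = 5, seed = 2)
  dev <- compute_deviations(
    clustering_coefficient(wl, "onnela"),
    char_path_length(wl, weighted = TRUE)$char_path_length,
    ns$c_latt, ns$c_rand, ns$l_latt, ns$l_rand)
  expect_lt(dev$delta_c, 0.05)   # a lattice matches its lattice null
  expect_gt(dev$delta_l, 0.9)    # and sits far from the random null in length

  rn <- random_null(wl, seed = 33)
  ns2 <- null_reference_stats(rn, n_realizations = 5, seed = 3)
  dev2 <- compute_deviations(
    clustering_coefficient(rn, "onnela"),
    char_path_length(rn, weighted = TRUE)$char_path_length,
    ns2$c_latt, ns2$c_rand, ns2$l_latt, ns2$l_rand)
  expect_lt(dev2$delta_l, 0.1)   # a shuffled network matches its random null
  expect_gt(dev2$delta_c, 0.8)
})
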