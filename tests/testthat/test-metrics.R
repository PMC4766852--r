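variants <- c("binary", "onnela", "barrat", "zhang")

test_that("clustering handles the elementary fixed cases", {
  k3 <- make_network(matrix(1, 3, 3) - diag(3))
  for (v in variants) {
    expect_equal(local_clustering(k3, v), c(1, 1, 1), info = v)
  }

  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  for (v in variants) {
    expect_equal(local_clustering(make_network(star), v), rep(0, 4), info = v)
  }

  # weighted triangle (1, 1, 1/8): every node's single neighbour pair
  # contributes (1 * 1 * 1/8)^(1/3) = 1/2 under the subgraph-intensity form
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[2, 3] <- w[3, 2] <- 1
  w[1, 3] <- w[3, 1] <- 1 / 8
  expect_equal(local_clustering(make_network(w), "onnela"), rep(0.5, 3))
})

test_that("ring-lattice clustering matches the closed form 3(r-1)/(2(2r-1))", {
  rl <- ring_lattice(1000, 5)
  expect_equal(clustering_coefficient(rl, "binary"), 2 / 3, tolerance = 1e-12)
  rl2 <- ring_lattice(101, 3)
  expect_equal(clustering_coefficient(rl2, "binary"), 3 * 2 / (2 * 5),
               tolerance = 1e-12)
})

test_that("all weighted variants reduce exactly to binary on binary networks", {
  set.seed(7)
  for (rep in 1:5) {
    net <- rand_net(10, p = 0.4, weighted = FALSE)
    cb <- local_clustering(net, "binary")
    for (v in c("onnela", "barrat", "zhang")) {
      expect_identical(local_clustering(net, v), cb, info = v)
    }
  }
})

test_that("clustering and path length match brute-force oracles for n <= 8", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(4:8, 1)
    net <- rand_net(n, p = 0.5, weighted = rep %% 2 == 0)
    w <- net$weights
    for (v in variants) {
      expect_equal(local_clustering(net, v), bf_local_clustering(w, v),
                   tolerance = 1e-12, info = paste(v, "rep", rep))
    }
    for (weighted in c(TRUE, FALSE)) {
      expect_equal(shortest_path_matrix(net, weighted = weighted),
                   bf_shortest_paths(w, weighted),
                   tolerance = 1e-12, info = paste("weighted =", weighted))
      cpl <- char_path_length(net, weighted = weighted)
      expect_equal(cpl$char_path_length, bf_char_path_length(w, weighted),
                   tolerance = 1e-12)
    }
  }
})

test_that("binary clustering agrees with igraph's local transitivity", {
  set.seed(5)
  net <- rand_net(40, p = 0.2, weighted = FALSE)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected")
  tr <- igraph::transitivity(g, type = "local")
  tr[is.nan(tr)] <- 0
  expect_equal(local_clustering(net, "binary"), tr, tolerance = 1e-12)
})

test_that("local coefficients stay in [0, 1]", {
  set.seed(13)
  for (rep in 1:10) {
    net <- rand_net(9, p = 0.5)
    net <- normalize_weights(net)
    for (v in variants) {
      ci <- local_clustering(net, v)
      expect_true(all(ci >= 0 & ci <= 1 + 1e-12), info = v)
    }
  }
})

test_that("weight rescaling leaves normalised clustering unchanged and scales distances", {
  set.seed(9)
  net <- rand_net(10)
  lambda <- 3.7
  scaled <- make_network(lambda * net$weights)
  for (v in c("onnela", "zhang")) {
    expect_equal(local_clustering(scaled, v), local_clustering(net, v),
                 tolerance = 1e-12, info = v)
  }
  expect_equal(shortest_path_matrix(scaled, weighted = TRUE),
               shortest_path_matrix(net, weighted = TRUE) / lambda,
               tolerance = 1e-12)
  expect_identical(local_clustering(scaled, "binary"),
                   local_clustering(net, "binary"))
})

test_that("distances use inverse-weight costs and pick multi-hop shortcuts", {
  two <- matrix(0, 2, 2)
  two[1, 2] <- two[2, 1] <- 2
  expect_equal(shortest_path_matrix(make_network(two))[1, 2], 0.5)

  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 1
  tri[1, 3] <- tri[3, 1] <- 0.25
  # direct edge costs 4; the two-hop path through node 2 costs 2
  expect_equal(shortest_path_matrix(make_network(tri))[1, 3], 2)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(shortest_path_matrix(make_network(path3), weighted = FALSE)[1, 3], 2)
  expect_equal(char_path_length(make_network(path3))$char_path_length, 4 / 3)
})

test_that("adding an edge never increases any shortest-path distance", {
  set.seed(17)
  for (rep in 1:8) {
    net <- rand_net(10, p = 0.25)
    d0 <- shortest_path_matrix(net, weighted = TRUE)
    w <- net$weights
    absent <- which(upper.tri(w) & w == 0, arr.ind = TRUE)
    if (nrow(absent) == 0) next
    pick <- absent[sample.int(nrow(absent), 1), ]
    w[pick[1], pick[2]] <- w[pick[2], pick[1]] <- stats::runif(1, 0.1, 2)
    d1 <- shortest_path_matrix(make_network(w), weighted = TRUE)
    expect_true(all(d1 <= d0 + 1e-12))
  }
})

test_that("disconnected networks report unreachable pairs; complete graphs have L = 1", {
  kn <- make_network(matrix(1, 5, 5) - diag(5))
  cpl <- char_path_length(kn)
  expect_equal(cpl$char_path_length, 1)
  expect_identical(cpl$n_unreachable_pairs, 0L)

  two_comp <- matrix(0, 4, 4)
  two_comp[1, 2] <- two_comp[2, 1] <- 1
  two_comp[3, 4] <- two_comp[4, 3] <- 1
  cpl2 <- char_path_length(make_network(two_comp))
  expect_identical(cpl2$n_unreachable_pairs, 8L)
  expect_equal(cpl2$char_path_length, 1)
  expect_error(char_path_length(make_network(two_comp), strict = TRUE),
               "unreachable")
})
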