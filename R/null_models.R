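#' Lattice null model conserving the observed weight multiset
#'
#' Builds the comparable weighted lattice for an observed network: the
#' observed edge weights are ranked in decreasing order and placed shell by
#' shell on a 1-D ring, so the strongest weights occupy the shortest lattice
#' distances. The distance-1 shell (capacity `n`) receives the strongest
#' weights, shuffled at random among its slots; the next-strongest weights
#' fill the distance-2 shell, and so on until all observed edges are placed.
#' Exact shell capacities are used (`n` slots per shell, `n/2` at the
#' antipodal distance for even `n`). Node count, edge count, and the exact
#' multiset of edge weights are conserved.
#'
#' Real networks carry no canonical 1-D layout; by default nodes sit on a
#' unit-spacing ring in index order. Because placement is by distance shell
#' rather than node identity, the null's summary statistics depend only weakly
#' on the ordering, but a layout can be supplied via `ordering` or a full
#' `distance_matrix` (e.g. Euclidean distances between recording sites), whose
#' sorted unique values then define the shells.
#'
#' @param net A `weighted_network`.
#' @param seed Optional integer seed controlling the within-shell shuffle.
#' @param ordering Optional permutation of `1:n` giving the ring layout.
#' @param distance_matrix Optional symmetric matrix of node-pair distances
#'   overriding the ring geometry.
#' @return A `weighted_network` with the same nodes and edge-weight multiset,
#'   maximally lattice-like.
#' @export
lattice_null <- function(net, seed = NULL, ordering = NULL,
                         distance_matrix = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  n <- net$n_nodes
  d <- if (is.null(distance_matrix)) {
    ring_distance_matrix(n, ordering)
  } else {
    stopifnot(is.matrix(distance_matrix), all(dim(distance_matrix) == n))
    distance_matrix
  }
  up <- upper.tri(net$weights)
  dvec <- d[up]
  wts <- sort(edge_weights(net), decreasing = TRUE)
  with_seed_if(seed, {
    slot_order <- order(dvec, stats::runif(length(dvec)))
    out <- numeric(length(dvec))
    out[slot_order[seq_along(wts)]] <- wts
    m <- matrix(0, n, n)
    m[up] <- out
    make_network(m + t(m))
  })
}

#' Random null model conserving the observed weight multiset
#'
#' The observed edge weights are redistributed uniformly at random: the
#' network's `E` weights are assigned, in random order, to `E` node pairs
#' drawn without replacement from all `n(n-1)/2` pairs. For a binary input
#' this is simply a uniform random graph with the same edge count.
#'
#' @param net A `weighted_network`.
#' @param seed Optional integer seed.
#' @return A `weighted_network` with the same nodes and edge-weight multiset,
#'   with low clustering and short paths.
#' @export
random_null <- function(net, seed = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  n <- net$n_nodes
  up <- upper.tri(net$weights)
  wts <- edge_weights(net)
  npairs <- sum(up)
  with_seed_if(seed, {
    slots <- sample.int(npairs, length(wts))
    out <- numeric(npairs)
    out[slots] <- wts[sample.int(length(wts))]
    m <- matrix(0, n, n)
    m[up] <- out
    make_network(m + t(m))
  })
}

#' Degree-preserving random null model (binary networks)
#'
#' Randomizes a binary network by repeated double-edge swaps that leave the
#' degree sequence exactly intact (`q * E` swap attempts). This is the
#' classical null for binary small-world comparisons, where the random
#' reference shares both size and degree distribution with the observation.
#' Weighted networks should use [random_null()] instead.
#'
#' @param net A binary `weighted_network`.
#' @param seed Optional integer seed.
#' @param q Swap attempts per edge (default 10).
#' @return A binary `weighted_network` with the same degree sequence.
#' @export
degree_preserving_null <- function(net, seed = NULL, q = 10) {
  stopifnot(inherits(net, "weighted_network"))
  if (!net$is_binary) {
    stop("degree-preserving randomization is defined for binary networks; ",
         "use random_null() for weighted networks", call. = FALSE)
  }
  with_seed_if(seed, {
    g <- as_igraph(net)
    g2 <- igraph::rewire(g, igraph::keeping_degseq(niter = q * igraph::ecount(g)))
    make_network(unname(igraph::as_adjacency_matrix(g2, sparse = FALSE)))
  })
}

#' Null-model reference statistics for an observed network
#'
#' Averages the clustering coefficient and characteristic path length of
#' lattice and random null realizations, producing the four anchors
#' (`c_latt`, `c_rand`, `l_latt`, `l_rand`) that normalise the observed
#' statistics. The lattice null supplies `c_latt` and `l_latt`; the random
#' null supplies `c_rand` and `l_rand`.
#'
#' By default the binary pipeline randomizes with the degree-preserving swap
#' null and the weighted pipeline with the weight-shuffling null, each the
#' conventional reference for its regime; `random_model` overrides.
#'
#' @param net A `weighted_network`.
#' @param n_realizations Null draws per model (default 10).
#' @param seed Optional master seed; per-draw seeds are derived by fixed
#'   offsets.
#' @param variant Clustering variant for weighted mode (see
#'   [local_clustering()]).
#' @param weighted Compute weighted statistics; defaults to `TRUE` for
#'   weighted networks.
#' @param random_model `"auto"` (degree-preserving when binary, weight
#'   shuffle otherwise), `"weight_shuffle"`, or `"degree_preserving"`.
#' @param ordering,distance_matrix Passed to [lattice_null()].
#' @return List of class `null_stats`: anchor means `c_latt`, `c_rand`,
#'   `l_latt`, `l_rand`, their standard errors (`*_se`), `n_realizations`,
#'   and the realized draws in `draws`.
#' @export
null_reference_stats <- function(net, n_realizations = 10, seed = NULL,
                                 variant = "onnela",
                                 weighted = !net$is_binary,
                                 random_model = c("auto", "weight_shuffle",
                                                  "degree_preserving"),
                                 ordering = NULL, distance_matrix = NULL) {
  stopifnot(inherits(net, "weighted_network"), n_realizations >= 1)
  random_model <- match.arg(random_model)
  if (random_model == "auto") {
    random_model <- if (net$is_binary) "degree_preserving" else "weight_shuffle"
  }
  cvar <- if (weighted) variant else "binary"
  draws <- lapply(seq_len(n_realizations), function(i) {
    s_latt <- if (is.null(seed)) NULL else seed + 2L * i
    s_rand <- if (is.null(seed)) NULL else seed + 2L * i + 1L
    latt <- lattice_null(net, seed = s_latt, ordering = ordering,
                         distance_matrix = distance_matrix)
    rand <- if (random_model == "degree_preserving") {
      degree_preserving_null(net, seed = s_rand)
    } else {
      random_null(net, seed = s_rand)
    }
    c(c_latt = clustering_coefficient(latt, cvar),
      c_rand = clustering_coefficient(rand, cvar),
      l_latt = char_path_length(latt, weighted = weighted)$char_path_length,
      l_rand = char_path_length(rand, weighted = weighted)$char_path_length)
  })
  draws <- do.call(rbind, draws)
  means <- colMeans(draws)
  ses <- apply(draws, 2, stats::sd) / sqrt(n_realizations)
  structure(
    c(as.list(means),
      stats::setNames(as.list(ses), paste0(colnames(draws), "_se")),
      list(n_realizations = n_realizations, random_model = random_model,
           draws = draws)),
    class = "null_stats"
  )
}

#' @export
print.null_stats <- function(x, ...) {
  cat(sprintf(
    paste0("null reference statistics (%d realizations, random model: %s)\n",
           "  C_latt = %.6g (se %.2g)   C_rand = %.6g (se %.2g)\n",
           "  L_latt = %.6g (se %.2g)   L_rand = %.6g (se %.2g)\n"),
    x$n_realizations, x$random_model,
    x$c_latt, x$c_latt_se, x$c_rand, x$c_rand_se,
    x$l_latt, x$l_latt_se, x$l_rand, x$l_rand_se))
  invisible(x)
}
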