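#' Binary ring lattice
#'
#' `n` nodes on a 1-D ring with unit spacing, each connected to every
#' neighbour within ring distance `r`, giving degree `2r` everywhere and
#' exactly `n * r` edges.
#'
#' @param n Number of nodes; must exceed `2 * r`.
#' @param r Lattice radius (each node links to its `r` nearest neighbours on
#'   either side).
#' @return A binary `weighted_network`.
#' @examples
#' ring_lattice(6, 1)  # the 6-cycle
#' @export
ring_lattice <- function(n, r) {
  check_lattice_params(n, r)
  d <- ring_distance_matrix(n)
  make_network((d >= 1 & d <= r) + 0)
}

#' Weighted ring lattice with distance-decaying edge weights
#'
#' Same topology as [ring_lattice()]; the weight of an edge decreases with the
#' ring distance between its endpoints, mimicking spatially embedded networks
#' in which nearby nodes are more strongly connected. The default rule is
#' \deqn{w(d) = (D_{max} - d) / D_{max}, \quad D_{max} = \max_{i,j} d_{ij} + \epsilon,}
#' where the maximum runs over all node pairs on the ring (`floor(n/2)`) and
#' \eqn{\epsilon} is one unit of lattice spacing, guaranteeing every edge a
#' strictly positive weight. For a lattice standing in for measured data,
#' \eqn{\epsilon} plays the role of the measurement precision.
#'
#' @inheritParams ring_lattice
#' @param epsilon Lattice-spacing increment added to the maximal ring distance
#'   (default 1, one unit of spacing).
#' @param weight_fn Optional replacement weight rule, a function of the
#'   integer ring distance returning a weight in `(0, 1]`; must be strictly
#'   decreasing over `1:r`.
#' @return A `weighted_network` with `n * r` edges whose weights strictly
#'   decrease with ring distance.
#' @export
weighted_ring_lattice <- function(n, r, epsilon = 1, weight_fn = NULL) {
  check_lattice_params(n, r)
  d_max <- floor(n / 2) + epsilon
  if (is.null(weight_fn)) weight_fn <- function(d) (d_max - d) / d_max
  wvals <- weight_fn(seq_len(r))
  if (any(wvals <= 0) || any(diff(wvals) >= 0)) {
    stop("`weight_fn` must be strictly decreasing and positive over 1..r",
         call. = FALSE)
  }
  d <- ring_distance_matrix(n)
  w <- matrix(0, n, n)
  on_edge <- d >= 1 & d <= r
  w[on_edge] <- weight_fn(d[on_edge])
  make_network(w)
}

#' Weight-preserving edge rewiring
#'
#' Each edge is independently selected with probability `p`; a selected edge
#' `(i, j)` (with `i < j`) is detached at `j` and reattached to a new endpoint
#' drawn uniformly among the nodes not already adjacent to `i`, carrying its
#' weight unchanged. The edge count and the multiset of edge weights are
#' conserved exactly for every `p` and seed. In the rare case that a kept
#' endpoint is already adjacent to every other node, the edge is left in
#' place with a warning.
#'
#' At `p = 0` the network is returned unchanged; at `p = 1` every edge is
#' relocated, producing a random topology with the original weight
#' distribution.
#'
#' @param net A `weighted_network`.
#' @param p Rewiring probability in `[0, 1]`.
#' @param seed Optional integer seed; the caller's RNG stream is not
#'   disturbed when a seed is given.
#' @return A `weighted_network` with identical edge count and weight multiset.
#' @export
rewire_edges <- function(net, p, seed = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop("`p` must be a probability in [0, 1]", call. = FALSE)
  }
  with_seed_if(seed, {
    w <- net$weights
    n <- net$n_nodes
    idx <- which(upper.tri(w) & w > 0)
    ei <- ((idx - 1) %% n) + 1
    ej <- ((idx - 1) %/% n) + 1
    sel <- stats::runif(length(idx)) < p
    saturated <- 0L
    for (e in which(sel)) {
      i <- ei[e]; j <- ej[e]
      wt <- w[i, j]
      w[i, j] <- w[j, i] <- 0
      cand <- which(w[i, ] == 0)
      cand <- cand[cand != i]
      if (length(cand) == 0L) {
        w[i, j] <- w[j, i] <- wt  # neighbourhood of i saturated; keep edge
        saturated <- saturated + 1L
        next
      }
      j2 <- cand[sample.int(length(cand), 1L)]
      w[i, j2] <- w[j2, i] <- wt
    }
    if (saturated > 0L) {
      warning(saturated, " edge(s) left in place: kept endpoint already ",
              "adjacent to all other nodes", call. = FALSE)
    }
    make_network(w)
  })
}

#' Binary Watts-Strogatz small-world network
#'
#' A [ring_lattice()] rewired with probability `p`: a lattice at `p = 0`, a
#' random network at `p = 1`, and a small-world network in between, where the
#' path length has already collapsed to near-random values while clustering
#' remains near-lattice.
#'
#' @inheritParams ring_lattice
#' @inheritParams rewire_edges
#' @return A binary `weighted_network`.
#' @export
watts_strogatz <- function(n, r, p, seed = NULL) {
  rewire_edges(ring_lattice(n, r), p, seed = seed)
}

#' Weighted Watts-Strogatz small-world network
#'
#' A [weighted_ring_lattice()] rewired with probability `p`; edges retain
#' their distance-derived weights as they are relocated, so the weight
#' distribution of the lattice is conserved along the whole transition from
#' lattice to random.
#'
#' @inheritParams weighted_ring_lattice
#' @inheritParams rewire_edges
#' @return A `weighted_network`.
#' @export
weighted_watts_strogatz <- function(n, r, p, seed = NULL, epsilon = 1,
                                    weight_fn = NULL) {
  rewire_edges(weighted_ring_lattice(n, r, epsilon = epsilon,
                                     weight_fn = weight_fn),
               p, seed = seed)
}

#' Hierarchical modular benchmark network
#'
#' Fractal construction on `2^mx_lv` nodes: base modules of `2^sz_cl` nodes
#' are fully connected with weight 1, and a pair of nodes whose lowest common
#' block sits `m` levels above the base is connected with probability
#' `E^-m` and, when connected, carries weight equal to that probability. The
#' intermediate matrix is directed (each ordered pair drawn independently) and
#' is reduced to an undirected network by [symmetrize_upper()]. The result is
#' strongly clustered at every scale but only weakly interconnected across
#' blocks, so weighted paths between distant modules are long.
#'
#' With `mx_lv = 10` and `sz_cl = 5, 6, 7` the construction yields 1024-node
#' networks with 5, 4, or 3 cross-hierarchy levels and expected weighted
#' (binary) densities of about 4.5 (10.8)%, 9.1 (18.7)% and 17.9 (31.2)%.
#'
#' @param sz_cl Base-module size exponent (module size `2^sz_cl`).
#' @param mx_lv Total depth exponent (network size `2^mx_lv`), default 10.
#' @param E Probability base: connection probability falls as `E^-m` per
#'   level above the base (default 2).
#' @param seed Optional integer seed.
#' @return A `weighted_network` on `2^mx_lv` nodes with weights in `(0, 1]`.
#' @export
hierarchical_modular_network <- function(sz_cl, mx_lv = 10, E = 2, seed = NULL) {
  if (!(mx_lv > sz_cl && sz_cl >= 1)) {
    stop("need mx_lv > sz_cl >= 1", call. = FALSE)
  }
  if (E <= 1) stop("probability base `E` must exceed 1", call. = FALSE)
  n <- 2^mx_lv
  idx <- 0:(n - 1)
  xo <- outer(idx, idx, bitwXor)
  # position of the highest differing bit = hierarchical level of the pair
  hb <- matrix(0, n, n)
  nz <- xo > 0
  hb[nz] <- floor(log2(xo[nz])) + 1
  m <- pmax(hb - sz_cl, 0)
  prob <- E^(-m)
  with_seed_if(seed, {
    placed <- matrix(stats::runif(n * n), n, n) < prob
    w <- matrix(0, n, n)
    w[placed] <- prob[placed]
    diag(w) <- 0
    symmetrize_upper(w)
  })
}

#' Modular benchmark network
#'
#' `2^(mx_lv - sz_cl)` fully connected modules of `2^sz_cl` nodes with
#' within-module weight 1, plus `k_edges` minus the within-module directed
#' edge count inter-module directed edges placed uniformly at random without
#' duplication, each with weight 0.5. The directed matrix is reduced to an
#' undirected network by [symmetrize_upper()]. The moderate-strength random
#' shortcuts keep weighted paths short while modules keep clustering high, so
#' these networks are strongly small-world at low shortcut counts.
#'
#' The default geometry (`mx_lv = 10`, `sz_cl = 6`) gives 16 modules of 64
#' nodes (64512 within-module directed edges, i.e. 32256 undirected edges
#' conserved exactly under symmetrization).
#'
#' @param k_edges Total directed edge budget `K`; must exceed the
#'   within-module count and fit the matrix.
#' @param sz_cl Module size exponent, default 6.
#' @param mx_lv Network size exponent, default 10.
#' @param seed Optional integer seed.
#' @return A `weighted_network` on `2^mx_lv` nodes with weights in {0.5, 1}.
#' @export
modular_network <- function(k_edges, sz_cl = 6, mx_lv = 10, seed = NULL) {
  if (!(mx_lv > sz_cl && sz_cl >= 1)) {
    stop("need mx_lv > sz_cl >= 1", call. = FALSE)
  }
  n <- 2^mx_lv
  msize <- 2^sz_cl
  module <- rep(seq_len(n / msize), each = msize)
  within_directed <- n * (msize - 1)
  inter_capacity <- n * (n - 1) - within_directed
  if (k_edges <= within_directed) {
    stop("`k_edges` must exceed the within-module directed edge count (",
         within_directed, ")", call. = FALSE)
  }
  if (k_edges > within_directed + inter_capacity) {
    stop("`k_edges` exceeds the directed-pair capacity of the network",
         call. = FALSE)
  }
  same <- outer(module, module, "==")
  w <- matrix(0, n, n)
  w[same] <- 1
  diag(w) <- 0
  with_seed_if(seed, {
    inter_idx <- which(!same)
    chosen <- inter_idx[sample.int(length(inter_idx), k_edges - within_directed)]
    w[chosen] <- 0.5
    symmetrize_upper(w)
  })
}

ring_distance_matrix <- function(n, ordering = NULL) {
  pos <- seq_len(n)
  if (!is.null(ordering)) {
    if (!setequal(ordering, seq_len(n)) || length(ordering) != n) {
      stop("`ordering` must be a permutation of 1..n", call. = FALSE)
    }
    pos[ordering] <- seq_len(n)
  }
  d <- abs(outer(pos, pos, "-"))
  pmin(d, n - d)
}

check_lattice_params <- function(n, r) {
  if (!(length(n) == 1 && length(r) == 1 && n == round(n) && r == round(r))) {
    stop("`n` and `r` must be integers", call. = FALSE)
  }
  if (!(r >= 1 && n > 2 * r)) {
    stop("need n > 2r and r >= 1; got n = ", n, ", r = ", r, call. = FALSE)
  }
  invisible(TRUE)
}
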