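# Independent brute-force oracles, deliberately naive: triple enumeration for
# clustering, Floyd-Warshall for shortest paths. Used only on small networks.

bf_local_clustering <- function(w, variant) {
  n <- nrow(w)
  a <- (w > 0) + 0
  k <- rowSums(a)
  wh <- w / max(w)
  vapply(seq_len(n), function(i) {
    num <- 0
    for (j in seq_len(n)) {
      for (h in seq_len(n)) {
        if (j == i || h == i || j == h) next
        num <- num + switch(variant,
          binary = a[i, j] * a[j, h] * a[h, i],
          onnela = (wh[i, j] * wh[j, h] * wh[h, i])^(1 / 3),
          barrat = ((w[i, j] + w[i, h]) / 2) * a[i, j] * a[i, h] * a[j, h],
          zhang  = wh[i, j] * wh[j, h] * wh[h, i]
        )
      }
    }
    den <- switch(variant,
      binary = k[i] * (k[i] - 1),
      onnela = k[i] * (k[i] - 1),
      barrat = sum(w[i, ]) * (k[i] - 1),
      zhang  = sum(wh[i, ])^2 - sum(wh[i, ]^2)
    )
    if (k[i] < 2 || den <= 0) 0 else num / den
  }, numeric(1))
}

bf_shortest_paths <- function(w, weighted) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- if (weighted) 1 / w[w > 0] else 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

bf_char_path_length <- function(w, weighted) {
  d <- bf_shortest_paths(w, weighted)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

# Random small test network with at least one edge.
rand_net <- function(n, p = 0.5, weighted = TRUE) {
  repeat {
    m <- matrix(0, n, n)
    up <- which(upper.tri(m))
    on <- stats::runif(length(up)) < p
    if (!any(on)) next
    m[up[on]] <- if (weighted) stats::runif(sum(on), 0.1, 2) else 1
    return(make_network(m + t(m)))
  }
}

sorted_weights <- function(net) sort(edge_weights(net))

# Logical mask of node pairs at ring distance == d (or <= d with within=TRUE).
ring_distance_at <- function(n, d, within = FALSE) {
  rd <- abs(outer(seq_len(n), seq_len(n), "-"))
  rd <- pmin(rd, n - rd)
  if (within) rd >= 1 & rd <= d else rd == d
}
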