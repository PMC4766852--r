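#' Local clustering coefficients
#'
#' Per-node triangle-closure coefficients \eqn{c_i}, in the binary form or in
#' one of three weighted generalisations. With \eqn{A} the binary adjacency,
#' \eqn{W} the weight matrix, \eqn{k_i} the degree, \eqn{s_i = \sum_j w_{ij}}
#' the strength, and \eqn{\hat w = w / \max(w)}:
#' \describe{
#'   \item{binary}{\eqn{c_i = (A^3)_{ii} / (k_i (k_i - 1))}: the fraction of
#'     pairs of neighbours of \eqn{i} that are themselves connected.}
#'   \item{onnela}{subgraph-intensity form
#'     \eqn{c_i = \frac{1}{k_i(k_i-1)} \sum_{j,h}
#'     (\hat w_{ij} \hat w_{jh} \hat w_{hi})^{1/3}}.}
#'   \item{barrat}{degree/strength form
#'     \eqn{c_i = \frac{1}{s_i(k_i-1)} \sum_{j,h}
#'     \frac{w_{ij} + w_{ih}}{2} a_{ij} a_{ih} a_{jh}}.}
#'   \item{zhang}{purely weight-based form
#'     \eqn{c_i = \sum_{j,h} \hat w_{ij} \hat w_{jh} \hat w_{hi} /
#'     ((\sum_j \hat w_{ij})^2 - \sum_j \hat w_{ij}^2)}.}
#' }
#' All weighted variants reduce exactly to the binary coefficient on a binary
#' network. Nodes with fewer than two neighbours (or a zero denominator) get
#' \eqn{c_i = 0} and are retained in averages, keeping the mean comparable
#' across networks with leaves.
#'
#' The normalisation \eqn{\hat w} uses the maximum weight of the matrix under
#' evaluation, so Onnela and Zhang coefficients are invariant under a common
#' positive rescaling of all weights.
#'
#' @param net A `weighted_network`.
#' @param variant One of `"onnela"` (default), `"binary"`, `"barrat"`,
#'   `"zhang"`.
#' @return Numeric vector of per-node coefficients.
#' @examples
#' w <- matrix(0, 3, 3)
#' w[1, 2] <- w[2, 1] <- 1; w[2, 3] <- w[3, 2] <- 1; w[1, 3] <- w[3, 1] <- 1/8
#' local_clustering(make_network(w), "onnela")  # 0.5 for every node
#' @export
local_clustering <- function(net, variant = c("onnela", "binary", "barrat", "zhang")) {
  stopifnot(inherits(net, "weighted_network"))
  variant <- match.arg(variant)
  w <- net$weights
  a <- (w > 0) + 0
  k <- rowSums(a)
  num <- den <- NULL
  switch(variant,
    binary = {
      num <- triangle_diag(a)
      den <- k * (k - 1)
    },
    onnela = {
      wh <- (w / max(w))^(1 / 3)
      num <- triangle_diag(wh)
      den <- k * (k - 1)
    },
    barrat = {
      # sum_{j,h} ((w_ij + w_ih)/2) a_ij a_ih a_jh collapses by j<->h symmetry
      # to sum_j w_ij (A^2)_ij
      num <- rowSums(w * (a %*% a))
      den <- rowSums(w) * (k - 1)
    },
    zhang = {
      wh <- w / max(w)
      num <- triangle_diag(wh)
      den <- rowSums(wh)^2 - rowSums(wh^2)
    }
  )
  ifelse(k >= 2 & den > 0, num / den, 0)
}

# (M^3)_ii for a symmetric matrix M, i.e. sum over ordered triangles at i.
triangle_diag <- function(m) {
  rowSums((m %*% m) * m)
}

#' Network clustering coefficient
#'
#' The mean of the per-node [local_clustering()] coefficients over all nodes,
#' including zero-degree nodes (which contribute 0).
#'
#' @inheritParams local_clustering
#' @return Scalar clustering coefficient `C`.
#' @export
clustering_coefficient <- function(net, variant = c("onnela", "binary", "barrat", "zhang")) {
  mean(local_clustering(net, variant))
}

#' All-pairs shortest-path distances
#'
#' In weighted mode, traversing an edge costs the reciprocal of its weight
#' (\eqn{d_{ij} = 1/w_{ij}}): strong edges are cheap to traverse, which is the
#' natural cost for networks whose weights measure connection strength or
#' similarity. In binary mode, distances are minimal hop counts.
#'
#' @param net A `weighted_network`.
#' @param weighted Use inverse-weight edge costs (default for weighted
#'   networks) or hop counts.
#' @return `n x n` matrix of minimal path costs; diagonal 0; `Inf` marks
#'   unreachable pairs.
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- w[2, 1] <- 2
#' shortest_path_matrix(make_network(w))[1, 2]  # 0.5
#' @export
shortest_path_matrix <- function(net, weighted = !net$is_binary) {
  stopifnot(inherits(net, "weighted_network"))
  g <- as_igraph(net)
  if (weighted) {
    d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight,
                           algorithm = "dijkstra")
  } else {
    d <- igraph::distances(g, weights = NA)
  }
  unname(d)
}

#' Characteristic path length
#'
#' Mean shortest-path distance over all ordered node pairs with a finite
#' distance. Unreachable pairs are excluded from the mean and reported in
#' `n_unreachable_pairs`, so the statistic stays well-defined on disconnected
#' networks; set `strict = TRUE` to escalate disconnection to an error.
#'
#' @inheritParams shortest_path_matrix
#' @param strict Error if any pair is unreachable.
#' @return List of class `path_stats` with `char_path_length` and
#'   `n_unreachable_pairs` (ordered pairs).
#' @examples
#' path3 <- matrix(0, 3, 3)
#' path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
#' char_path_length(make_network(path3))$char_path_length  # 4/3
#' @export
char_path_length <- function(net, weighted = !net$is_binary, strict = FALSE) {
  d <- shortest_path_matrix(net, weighted = weighted)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  n_unreach <- sum(!finite)
  if (n_unreach > 0 && strict) {
    stop(n_unreach, " ordered node pairs are unreachable", call. = FALSE)
  }
  if (!any(finite)) {
    stop("degenerate network: no finite off-diagonal distance", call. = FALSE)
  }
  structure(
    list(char_path_length = mean(off[finite]), n_unreachable_pairs = n_unreach),
    class = "path_stats"
  )
}

#' @export
print.path_stats <- function(x, ...) {
  cat(sprintf("characteristic path length: %.6g (%d unreachable ordered pairs)\n",
              x$char_path_length, x$n_unreachable_pairs))
  invisible(x)
}
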