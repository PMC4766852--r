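#' Construct a weighted network from a symmetric adjacency matrix
#'
#' The canonical carrier used throughout the package: an undirected network on
#' `n` nodes stored as a dense symmetric matrix of nonnegative edge weights
#' with a zero diagonal. An entry is an edge iff its weight is strictly
#' positive; no epsilon thresholding is applied.
#'
#' @param x Square numeric matrix with finite, nonnegative entries. Must be
#'   exactly symmetric unless `symmetrize = TRUE`.
#' @param symmetrize If `TRUE`, an asymmetric (e.g. directed) matrix is
#'   accepted and reduced to an undirected network by keeping only its strict
#'   upper triangle (see [symmetrize_upper()]).
#'
#' @return An object of class `weighted_network`: a list with elements
#'   `weights` (the symmetric matrix), `n_nodes`, and `is_binary` (`TRUE` iff
#'   every nonzero weight equals 1).
#'
#' @details Self-loops (nonzero diagonal entries) are stripped with a warning;
#'   none of the supported network models admit them. A matrix with no edges
#'   at all is rejected as degenerate.
#'
#' @examples
#' tri <- matrix(1, 3, 3) - diag(3)
#' net <- make_network(tri)
#' net$is_binary
#' @export
make_network <- function(x, symmetrize = FALSE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) != ncol(x)) {
    stop("adjacency matrix must be square, got ", nrow(x), " x ", ncol(x),
         call. = FALSE)
  }
  if (nrow(x) < 2) stop("a network needs at least 2 nodes", call. = FALSE)
  if (any(!is.finite(x))) {
    stop("adjacency entries must be finite", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("adjacency entries must be nonnegative; negative weights are not supported",
         call. = FALSE)
  }
  if (symmetrize) return(symmetrize_upper(x))
  if (any(x != t(x))) {
    stop("matrix is not symmetric; pass symmetrize = TRUE (or use symmetrize_upper()) ",
         "to reduce a directed matrix to its upper triangle", call. = FALSE)
  }
  x <- unname(x)
  storage.mode(x) <- "double"
  if (any(diag(x) != 0)) {
    warning("self-loops found on the diagonal; stripped", call. = FALSE)
    diag(x) <- 0
  }
  nz <- x[x > 0]
  if (length(nz) == 0) {
    stop("degenerate network: no edges", call. = FALSE)
  }
  structure(
    list(weights = x, n_nodes = nrow(x), is_binary = all(nz == 1)),
    class = "weighted_network"
  )
}

#' Symmetrize a directed matrix by its upper triangle
#'
#' Reduces a directed adjacency matrix to an undirected network by keeping the
#' strict upper triangle and mirroring it; the lower triangle and diagonal of
#' the input are discarded. This is the symmetrization convention used by the
#' benchmark generators, whose intermediate matrices are directed.
#'
#' @param x Square numeric matrix, finite and nonnegative.
#' @return A [make_network()] object with
#'   `weights[i, j] == weights[j, i] == x[i, j]` for `i < j`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 2] <- 0.5; m[2, 1] <- 0.9  # lower entry dropped
#' symmetrize_upper(m)$weights[1, 2]
#' @export
symmetrize_upper <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("`x` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(x) != ncol(x)) {
    stop("matrix must be square, got ", nrow(x), " x ", ncol(x), call. = FALSE)
  }
  if (any(!is.finite(x))) stop("entries must be finite", call. = FALSE)
  if (any(x < 0)) stop("entries must be nonnegative", call. = FALSE)
  u <- unname(x)
  u[lower.tri(u, diag = TRUE)] <- 0
  make_network(u + t(u))
}

#' Binary and weighted network density
#'
#' @param net A `weighted_network`.
#' @return A list of class `density_report` with `binary_density` (fraction of
#'   realized undirected edges among `n(n-1)/2` possible pairs) and
#'   `weighted_density` (sum of edge weights over the same denominator). The
#'   two coincide for binary networks, and `binary_density >=
#'   weighted_density` whenever all weights are at most 1.
#' @examples
#' k4 <- make_network(0.5 * (matrix(1, 4, 4) - diag(4)))
#' network_density(k4)
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  u <- net$weights[upper.tri(net$weights)]
  m <- length(u)
  structure(
    list(binary_density = sum(u > 0) / m, weighted_density = sum(u) / m),
    class = "density_report"
  )
}

#' Rescale edge weights to the unit interval
#'
#' Divides all weights by the maximum weight so the strongest edge has weight
#' 1. Offered as an explicit preprocessing step for empirical matrices whose
#' weights live on an arbitrary scale; it is never applied implicitly.
#'
#' @param net A `weighted_network`.
#' @return A `weighted_network` with max weight 1.
#' @export
normalize_weights <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  make_network(net$weights / max(net$weights))
}

#' Extract the multiset of edge weights
#'
#' @param net A `weighted_network`.
#' @return Numeric vector of the weights of all undirected edges (upper
#'   triangle, nonzero entries), in column-major order.
#' @export
edge_weights <- function(net) {
  stopifnot(inherits(net, "weighted_network"))
  u <- net$weights[upper.tri(net$weights)]
  u[u > 0]
}

#' @export
as.matrix.weighted_network <- function(x, ...) x$weights

#' @export
print.weighted_network <- function(x, ...) {
  d <- network_density(x)
  cat(sprintf(
    "<weighted_network> %d nodes, %d edges (%s), binary density %.4f, weighted density %.4f\n",
    x$n_nodes, length(edge_weights(x)),
    if (x$is_binary) "binary" else "weighted",
    d$binary_density, d$weighted_density
  ))
  invisible(x)
}

#' @export
print.density_report <- function(x, ...) {
  cat(sprintf("binary density:   %.6f\nweighted density: %.6f\n",
              x$binary_density, x$weighted_density))
  invisible(x)
}

# igraph view of a network; weights carried as the 'weight' edge attribute.
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

# Run code under a fixed seed without disturbing the caller's RNG stream;
# seed = NULL means "use the current stream".
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
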