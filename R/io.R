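#' Read an adjacency matrix or edge list from a text file
#'
#' Connectome matrices circulate in inconsistent dialects, so the format,
#' delimiter, header and index base are explicit. Two formats are supported:
#' \describe{
#'   \item{dense}{a square numeric matrix, one row per line, no header by
#'     default; comma, tab or whitespace separated.}
#'   \item{edgelist}{three columns `(node_i, node_j, weight)`; node indices
#'     0- or 1-based via `index_base` (default 0). Opposing duplicate entries
#'     `(i, j)` / `(j, i)` must agree within `1e-9` or the read fails.}
#' }
#'
#' @param path File to read.
#' @param format `"auto"` (by extension/shape), `"dense"` or `"edgelist"`.
#' @param sep Field separator; `""` (default) accepts any whitespace for
#'   dense files and tab for edge lists; dense `.csv` files default to comma.
#' @param index_base 0 or 1: the base of node indices in an edge list.
#' @param n_nodes Optional node count for edge lists (otherwise the maximum
#'   index seen).
#' @param symmetrize Accept a directed dense matrix by keeping its upper
#'   triangle.
#' @return A `weighted_network`.
#' @export
read_adjacency <- function(path, format = c("auto", "dense", "edgelist"),
                           sep = "", index_base = 0, n_nodes = NULL,
                           symmetrize = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- guess_sep(path, sep)
  tab <- utils::read.table(path, sep = sep, header = FALSE)
  if (format == "auto") {
    # a square table is read as a dense matrix; pass format = "edgelist"
    # explicitly for a 3-edge list on 3 nodes
    format <- if (nrow(tab) == ncol(tab)) "dense"
              else if (ncol(tab) == 3) "edgelist"
              else stop("cannot infer format from shape ", nrow(tab), " x ",
                        ncol(tab), "; pass `format`", call. = FALSE)
  }
  if (format == "dense") {
    m <- as.matrix(tab)
    if (!is.numeric(m)) stop("dense adjacency file must be all-numeric",
                             call. = FALSE)
    return(make_network(m, symmetrize = symmetrize))
  }
  if (ncol(tab) != 3) {
    stop("edge list must have 3 columns (node_i, node_j, weight), got ",
         ncol(tab), call. = FALSE)
  }
  i <- tab[[1]] - index_base + 1L
  j <- tab[[2]] - index_base + 1L
  w <- tab[[3]]
  if (any(i < 1 | j < 1)) {
    stop("node index below the declared index_base (", index_base, ")",
         call. = FALSE)
  }
  if (any(w < 0)) stop("negative edge weights are not supported", call. = FALSE)
  n <- if (is.null(n_nodes)) max(i, j) else n_nodes
  m <- matrix(0, n, n)
  seen <- matrix(FALSE, n, n)
  for (e in seq_along(i)) {
    a <- i[e]; b <- j[e]
    if (a == b) next  # self-loops dropped, as in make_network
    if (seen[a, b] && abs(m[a, b] - w[e]) > 1e-9) {
      stop(sprintf("conflicting duplicate entries for edge (%d, %d): %g vs %g",
                   a - 1L + index_base, b - 1L + index_base, m[a, b], w[e]),
           call. = FALSE)
    }
    m[a, b] <- m[b, a] <- w[e]
    seen[a, b] <- seen[b, a] <- TRUE
  }
  make_network(m)
}

guess_sep <- function(path, sep) {
  if (nzchar(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
}

#' Write a network to a text file
#'
#' @param net A `weighted_network`.
#' @param path Output file.
#' @param format `"dense"` (CSV square matrix, no header) or `"edgelist"`
#'   (TSV `(node_i, node_j, weight)` triples over the upper triangle).
#' @param index_base Index base for edge lists (default 0).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("dense", "edgelist"),
                          index_base = 0) {
  stopifnot(inherits(net, "weighted_network"))
  format <- match.arg(format)
  fmt <- function(x) formatC(x, format = "g", digits = 17)  # lossless doubles
  if (format == "dense") {
    utils::write.table(fmt(net$weights), path, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    idx <- which(upper.tri(net$weights) & net$weights > 0, arr.ind = TRUE)
    df <- data.frame(i = idx[, 1] - 1L + index_base,
                     j = idx[, 2] - 1L + index_base,
                     w = fmt(net$weights[idx]))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a machine-readable SWP report
#'
#' Serialises an [swp()] result to JSON: the headline statistics, the raw and
#' clamped deviations with clamp flags, the null anchors with standard errors,
#' and the provenance (seed, null draw count, clustering variant), plus a
#' one-line human-readable summary. Two runs with identical configuration and
#' seed produce identical reports.
#'
#' @param result An `swp_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "swp_result"))
  d <- result$deviations
  rep <- list(
    summary = sprintf(
      "phi = %.4f (%s at threshold %.2f); delta = %+.4f; delta_C = %.4f; delta_L = %.4f",
      result$phi, if (result$is_small_world) "small-world" else "not small-world",
      result$phi_threshold, result$delta, d$delta_c, d$delta_l),
    phi = result$phi,
    delta = result$delta,
    theta = result$theta,
    sigma = result$sigma,
    is_small_world = result$is_small_world,
    phi_threshold = result$phi_threshold,
    deviations = list(delta_c = d$delta_c, delta_l = d$delta_l,
                      raw_delta_c = d$raw_delta_c, raw_delta_l = d$raw_delta_l,
                      clamped_c = d$clamped_c, clamped_l = d$clamped_l),
    observed = list(c_obs = d$c_obs, l_obs = d$l_obs),
    anchors = list(c_latt = d$c_latt, c_rand = d$c_rand,
                   l_latt = d$l_latt, l_rand = d$l_rand),
    null_se = if (!is.null(result$nulls)) {
      result$nulls[c("c_latt_se", "c_rand_se", "l_latt_se", "l_rand_se")]
    },
    provenance = result$provenance
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a report written by [write_report()]
#'
#' @param path Report file.
#' @return A list mirroring the JSON structure.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Benchmark network suite
#'
#' Generates the standard validation networks in one call: the three
#' hierarchical-modular networks (`sz_cl = 5, 6, 7`; low/medium/high density),
#' the three modular networks (`k_edges = 65000, 100000, 150000`), all on 1024
#' nodes, and optionally binary and weighted Watts-Strogatz ladders
#' (`n = 1000`, `r = 5`) over a rewiring-probability grid.
#'
#' @param seed Master seed; each network gets a derived seed.
#' @param include_ws Also build the Watts-Strogatz ladders (default `FALSE`;
#'   they dominate the memory footprint).
#' @param p_grid Grid for the ladders.
#' @return Named list of `weighted_network` objects: `hn_low`, `hn_medium`,
#'   `hn_high`, `mn_low`, `mn_medium`, `mn_high`, and (when requested)
#'   `ws_binary` / `ws_weighted`, lists indexed by `p`.
#' @export
fixture_suite <- function(seed = 1, include_ws = FALSE,
                          p_grid = c(0, 0.001, 0.01, 0.02, 0.1, 1)) {
  out <- list(
    hn_low = hierarchical_modular_network(sz_cl = 5, seed = seed + 1L),
    hn_medium = hierarchical_modular_network(sz_cl = 6, seed = seed + 2L),
    hn_high = hierarchical_modular_network(sz_cl = 7, seed = seed + 3L),
    mn_low = modular_network(65000, seed = seed + 4L),
    mn_medium = modular_network(100000, seed = seed + 5L),
    mn_high = modular_network(150000, seed = seed + 6L)
  )
  if (include_ws) {
    mk <- function(gen) {
      nets <- lapply(seq_along(p_grid), function(i) {
        gen(p_grid[i], seed + 100L + i)
      })
      names(nets) <- paste0("p=", p_grid)
      nets
    }
    out$ws_binary <- mk(function(p, s) watts_strogatz(1000, 5, p, seed = s))
    out$ws_weighted <- mk(function(p, s) weighted_watts_strogatz(1000, 5, p, seed = s))
  }
  out
}

#' Mean benchmark densities over seeds
#'
#' Regenerates each benchmark family configuration `n_seeds` times and
#' averages the binary and weighted densities (in percent), the standard
#' validation table for the generators.
#'
#' @param n_seeds Seeds per configuration (default 10).
#' @param seed Master seed.
#' @return Data frame with columns `family`, `config`, `param`,
#'   `binary_density_pct`, `weighted_density_pct`.
#' @export
benchmark_density_table <- function(n_seeds = 10, seed = 1) {
  configs <- list(
    list(family = "HN", config = "low",    gen = function(s) hierarchical_modular_network(5, seed = s), param = "sz_cl=5"),
    list(family = "HN", config = "medium", gen = function(s) hierarchical_modular_network(6, seed = s), param = "sz_cl=6"),
    list(family = "HN", config = "high",   gen = function(s) hierarchical_modular_network(7, seed = s), param = "sz_cl=7"),
    list(family = "MN", config = "low",    gen = function(s) modular_network(65000, seed = s),  param = "K=65000"),
    list(family = "MN", config = "medium", gen = function(s) modular_network(100000, seed = s), param = "K=100000"),
    list(family = "MN", config = "high",   gen = function(s) modular_network(150000, seed = s), param = "K=150000")
  )
  rows <- lapply(configs, function(cf) {
    dens <- vapply(seq_len(n_seeds), function(k) {
      d <- network_density(cf$gen(seed + 37L * k))
      c(d$binary_density, d$weighted_density)
    }, numeric(2))
    data.frame(family = cf$family, config = cf$config, param = cf$param,
               binary_density_pct = 100 * mean(dens[1, ]),
               weighted_density_pct = 100 * mean(dens[2, ]))
  })
  do.call(rbind, rows)
}
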