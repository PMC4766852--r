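#' Normalised deviations from the lattice and random nulls
#'
#' The two bounded ratios at the heart of the Small-World Propensity:
#' \deqn{\Delta_C = \frac{C_{latt} - C_{obs}}{C_{latt} - C_{rand}}, \qquad
#'       \Delta_L = \frac{L_{obs} - L_{rand}}{L_{latt} - L_{rand}},}
#' each the fractional deviation of an observed statistic from its ideal null
#' (lattice for clustering, random for path length), normalised by the range
#' the nulls span at the observed density. Observed networks can fall outside
#' the null range, so both ratios are clamped to `[0, 1]`; the raw values and
#' clamp flags are retained for diagnostics.
#'
#' @param c_obs,l_obs Observed clustering coefficient and path length.
#' @param c_latt,c_rand,l_latt,l_rand Null anchors.
#' @return List of class `deviation_pair` with `delta_c`, `delta_l` (clamped),
#'   `raw_delta_c`, `raw_delta_l`, logical `clamped_c`, `clamped_l`, and the
#'   six raw statistics.
#' @examples
#' compute_deviations(c_obs = 0.6, l_obs = 3.1,
#'                    c_latt = 0.67, c_rand = 0.01, l_latt = 50, l_rand = 3)
#' @export
compute_deviations <- function(c_obs, l_obs, c_latt, c_rand, l_latt, l_rand) {
  vals <- c(c_obs, l_obs, c_latt, c_rand, l_latt, l_rand)
  if (length(vals) != 6 || any(!is.finite(vals))) {
    stop("all six statistics must be finite scalars", call. = FALSE)
  }
  if (c_latt == c_rand) {
    stop("degenerate clustering range: C_latt == C_rand (", c_latt,
         "); deviations are undefined", call. = FALSE)
  }
  if (l_latt == l_rand) {
    stop("degenerate path-length range: L_latt == L_rand (", l_latt,
         "); deviations are undefined", call. = FALSE)
  }
  raw_dc <- unname((c_latt - c_obs) / (c_latt - c_rand))
  raw_dl <- unname((l_obs - l_rand) / (l_latt - l_rand))
  structure(
    list(delta_c = min(max(raw_dc, 0), 1),
         delta_l = min(max(raw_dl, 0), 1),
         raw_delta_c = raw_dc, raw_delta_l = raw_dl,
         clamped_c = raw_dc < 0 || raw_dc > 1,
         clamped_l = raw_dl < 0 || raw_dl > 1,
         c_obs = c_obs, l_obs = l_obs, c_latt = c_latt, c_rand = c_rand,
         l_latt = l_latt, l_rand = l_rand),
    class = "deviation_pair"
  )
}

#' Small-World Propensity
#'
#' \deqn{\phi = 1 - \sqrt{\frac{\Delta_C^2 + \Delta_L^2}{2}}.}
#' With both deviations clamped to `[0, 1]`, \eqn{\phi} is bounded in
#' `[0, 1]`: 1 at the small-world ideal (lattice-like clustering and
#' random-like path length), 0 when both deviations are maximal, and
#' \eqn{1 - \sqrt{1/2} \approx 0.29} at the pure-lattice and pure-random
#' corners `(0, 1)` and `(1, 0)`.
#'
#' @param delta_c A `deviation_pair` from [compute_deviations()], or the
#'   clamped clustering deviation as a scalar.
#' @param delta_l Clamped path-length deviation (ignored when `delta_c` is a
#'   `deviation_pair`).
#' @return Scalar \eqn{\phi \in [0, 1]}.
#' @examples
#' small_world_propensity(0, 1)  # 1 - sqrt(1/2)
#' @export
small_world_propensity <- function(delta_c, delta_l = NULL) {
  d <- as_delta_pair(delta_c, delta_l)
  1 - sqrt((d[1]^2 + d[2]^2) / 2)
}

#' Contribution to deviation
#'
#' Summarises which deviation drives a network away from the small-world
#' ideal. With \eqn{\theta = \arctan(\Delta_L / \Delta_C)} the angle of the
#' \eqn{(\Delta_C, \Delta_L)} vector (\eqn{\theta = \pi/2} when
#' \eqn{\Delta_C = 0}), the angular offset from the equal-contribution
#' diagonal is mapped linearly onto `[-1, 1]`:
#' \deqn{\delta = \frac{4\theta}{\pi} - 1.}
#' \eqn{\delta = 1} when the deficit is entirely path-length-driven
#' (\eqn{\Delta_L = 1, \Delta_C = 0}), \eqn{-1} when entirely
#' clustering-driven, and 0 on the diagonal of equal contribution. \eqn{\delta}
#' depends only on the direction of the deviation vector, not its length. At
#' the degenerate origin `(0, 0)` the angle is undefined and \eqn{\delta} is
#' set to 0 by symmetry (equal contribution).
#'
#' @inheritParams small_world_propensity
#' @return Scalar \eqn{\delta \in [-1, 1]}.
#' @examples
#' contribution_to_deviation(0, 1)  #  1: path-length-driven
#' contribution_to_deviation(1, 0)  # -1: clustering-driven
#' @export
contribution_to_deviation <- function(delta_c, delta_l = NULL) {
  d <- as_delta_pair(delta_c, delta_l)
  4 * deviation_angle(d[1], d[2]) / pi - 1
}

deviation_angle <- function(dc, dl) {
  if (dc == 0 && dl == 0) return(pi / 4)  # degenerate origin: equal contribution
  if (dc == 0) return(pi / 2)
  atan(dl / dc)
}

as_delta_pair <- function(delta_c, delta_l) {
  if (inherits(delta_c, "deviation_pair")) {
    return(c(delta_c$delta_c, delta_c$delta_l))
  }
  if (is.null(delta_l)) {
    stop("supply a deviation_pair or both `delta_c` and `delta_l`",
         call. = FALSE)
  }
  stopifnot(is.numeric(delta_c), is.numeric(delta_l),
            length(delta_c) == 1, length(delta_l) == 1)
  if (delta_c < 0 || delta_c > 1 || delta_l < 0 || delta_l > 1) {
    stop("deviations must lie in [0, 1] (clamp with compute_deviations())",
         call. = FALSE)
  }
  c(delta_c, delta_l)
}

#' Classical small-world index
#'
#' The widely used ratio-of-ratios
#' \eqn{\sigma = (C_{obs}/C_{rand}) / (L_{obs}/L_{rand})}, with values above 1
#' conventionally read as small-world. Provided for comparison: unlike the
#' Small-World Propensity, \eqn{\sigma} is strongly density dependent and has
#' no upper bound.
#'
#' @param c_obs,c_rand Observed and random-null clustering coefficients.
#' @param l_obs,l_rand Observed and random-null path lengths.
#' @return Scalar \eqn{\sigma > 0}.
#' @export
small_world_index <- function(c_obs, c_rand, l_obs, l_rand) {
  if (c_rand <= 0 || l_rand <= 0 || l_obs <= 0) {
    stop("small-world index requires positive C_rand, L_obs and L_rand",
         call. = FALSE)
  }
  unname((c_obs / c_rand) / (l_obs / l_rand))
}

#' Small-World Propensity of an observed network
#'
#' The end-to-end pipeline: computes the observed clustering coefficient and
#' characteristic path length, builds lattice and random null references that
#' conserve the observed edge-weight multiset (see
#' [null_reference_stats()]), and derives the deviations \eqn{\Delta_C},
#' \eqn{\Delta_L}, the propensity \eqn{\phi}, the contribution-to-deviation
#' \eqn{\delta}, and the comparison index \eqn{\sigma}. The run is
#' deterministic given `seed`.
#'
#' For networks generated from a parametrised family whose lattice and random
#' endpoints are known (e.g. a Watts-Strogatz ensemble, where the lattice is
#' the `p = 0` network and the random reference the `p = 1` ensemble), the
#' anchors can be supplied directly via `anchors`, bypassing null
#' construction.
#'
#' @param net A `weighted_network`.
#' @param n_realizations Null draws per model.
#' @param seed Optional master seed.
#' @param variant Weighted clustering variant (default `"onnela"`).
#' @param weighted Compute weighted statistics; defaults to `TRUE` for
#'   weighted networks.
#' @param phi_threshold Reference threshold \eqn{\phi_T} above which a network
#'   is flagged as small-world (default 0.6, a pragmatic convention; the
#'   statistic itself is continuous).
#' @param anchors Optional list with `c_latt`, `c_rand`, `l_latt`, `l_rand`
#'   overriding null construction.
#' @param random_model,ordering,distance_matrix Passed to
#'   [null_reference_stats()].
#' @return An object of class `swp_result`: `phi`, `delta`, `theta`, `sigma`,
#'   the `deviation_pair` in `deviations`, `is_small_world`, `phi_threshold`,
#'   null summaries in `nulls`, and `provenance` (seed, draw count, variant,
#'   weighted flag).
#' @examples
#' net <- weighted_watts_strogatz(100, 4, p = 0.05, seed = 7)
#' swp(net, n_realizations = 3, seed = 1)
#' @export
swp <- function(net, n_realizations = 10, seed = NULL, variant = "onnela",
                weighted = !net$is_binary, phi_threshold = 0.6,
                anchors = NULL, random_model = "auto", ordering = NULL,
                distance_matrix = NULL) {
  stopifnot(inherits(net, "weighted_network"))
  cvar <- if (weighted) variant else "binary"
  c_obs <- clustering_coefficient(net, cvar)
  l_obs <- char_path_length(net, weighted = weighted)$char_path_length
  nulls <- NULL
  if (is.null(anchors)) {
    nulls <- null_reference_stats(net, n_realizations = n_realizations,
                                  seed = seed, variant = variant,
                                  weighted = weighted,
                                  random_model = random_model,
                                  ordering = ordering,
                                  distance_matrix = distance_matrix)
    anchors <- nulls[c("c_latt", "c_rand", "l_latt", "l_rand")]
  } else {
    stopifnot(all(c("c_latt", "c_rand", "l_latt", "l_rand") %in% names(anchors)))
  }
  dev <- compute_deviations(c_obs, l_obs, anchors$c_latt, anchors$c_rand,
                            anchors$l_latt, anchors$l_rand)
  phi <- small_world_propensity(dev)
  sigma <- if (anchors$c_rand > 0 && anchors$l_rand > 0 && l_obs > 0) {
    small_world_index(c_obs, anchors$c_rand, l_obs, anchors$l_rand)
  } else {
    NA_real_
  }
  structure(
    list(phi = phi,
         delta = contribution_to_deviation(dev),
         theta = deviation_angle(dev$delta_c, dev$delta_l),
         sigma = sigma,
         degenerate_angle = dev$delta_c == 0 && dev$delta_l == 0,
         deviations = dev,
         is_small_world = phi > phi_threshold,
         phi_threshold = phi_threshold,
         nulls = nulls,
         provenance = list(seed = seed, n_realizations = n_realizations,
                           variant = cvar, weighted = weighted)),
    class = "swp_result"
  )
}

#' @export
print.swp_result <- function(x, ...) {
  d <- x$deviations
  cat(sprintf(
    paste0("Small-World Propensity\n",
           "  phi   = %.4f  (%s, threshold %.2f)\n",
           "  delta = %+.4f  (theta = %.4f rad)\n",
           "  delta_C = %.4f%s   delta_L = %.4f%s\n",
           "  C_obs = %.6g  [C_latt = %.6g, C_rand = %.6g]\n",
           "  L_obs = %.6g  [L_latt = %.6g, L_rand = %.6g]\n",
           "  sigma = %.4g   (%s statistics, %s clustering)\n"),
    x$phi, if (x$is_small_world) "small-world" else "not small-world",
    x$phi_threshold, x$delta, x$theta,
    d$delta_c, if (d$clamped_c) " [clamped]" else "",
    d$delta_l, if (d$clamped_l) " [clamped]" else "",
    d$c_obs, d$c_latt, d$c_rand, d$l_obs, d$l_latt, d$l_rand,
    x$sigma, if (x$provenance$weighted) "weighted" else "binary",
    x$provenance$variant))
  invisible(x)
}

#' @export
print.deviation_pair <- function(x, ...) {
  cat(sprintf("delta_C = %.4f%s  delta_L = %.4f%s  (raw: %.4g, %.4g)\n",
              x$delta_c, if (x$clamped_c) " [clamped]" else "",
              x$delta_l, if (x$clamped_l) " [clamped]" else "",
              x$raw_delta_c, x$raw_delta_l))
  invisible(x)
}
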