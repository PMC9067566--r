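# Steinhardt bond-orientational order parameters.
#
# For molecule i with neighbours N(i):
#   q_lm(i) = (1/|N(i)|) sum_{j in N(i)} Y_lm(r_hat_ij)
#   q_l(i)  = sqrt( 4 pi / (2l+1) * sum_{m=-l..l} |q_lm(i)|^2 )
# Only m >= 0 is stored; the m < 0 terms follow from
# Y_{l,-m} = (-1)^m conj(Y_lm), a relation that is linear and therefore
# survives the neighbourhood averaging used by the locally-averaged variant.

# normalised spherical harmonics Y_lm for m = 0..l at the given unit vectors,
# returned as a (n x (l+1)) complex matrix
spherical_harmonics <- function(l, u) {
  ct <- pmin(pmax(u[, 3], -1), 1)
  phi <- atan2(u[, 2], u[, 1])
  if (l == 0L) {
    return(matrix(complex(real = rep(1 / sqrt(4 * pi), nrow(u))), ncol = 1L))
  }
  P <- pracma::legendre(l, ct)  # (l+1) x n, includes the Condon-Shortley phase
  m <- 0:l
  norm <- sqrt((2 * l + 1) / (4 * pi) *
                 exp(lfactorial(l - m) - lfactorial(l + m)))
  Y <- matrix(0 + 0i, nrow(u), l + 1L)
  for (k in seq_along(m)) {
    Y[, k] <- norm[k] * P[k, ] * exp(1i * m[k] * phi)
  }
  Y
}

#' Steinhardt bond-orientational order parameter q_l
#'
#' Computes per-atom q_l values from the bond directions of a neighbour
#' graph.  Atoms with no neighbours get `NA` (flagged undefined, never a
#' silent zero).  For water systems, call this on the oxygen-only
#' configuration ([water_oxygen_config()]): hydrogens are ignored and each
#' molecule is represented by its oxygen.
#'
#' @param config The [configuration] the graph was built on.
#' @param graph A [neighbor_list()] result for `config`.
#' @param l Spherical-harmonic order (non-negative integer); `l = 0` gives
#'   q_0 = 1 wherever defined.
#' @return An object of class `order_parameter_set`: `q` (numeric, `NA`
#'   where undefined), `qlm` (complex n x (l+1) matrix, m = 0..l),
#'   `n_neighbors`, `l`, and a `variant` tag (`"q"`).
#' @export
steinhardt_q <- function(config, graph, l = 6L) {
  stopifnot(inherits(config, "configuration"), inherits(graph, "neighbor_graph"))
  if (graph$n_atoms != n_atoms(config)) {
    stop("graph and configuration disagree on atom count")
  }
  if (!is.numeric(l) || length(l) != 1L || l < 0 || l != round(l)) {
    stop("'l' must be a non-negative integer")
  }
  l <- as.integer(l)
  n <- n_atoms(config)
  p <- graph$pairs
  nb <- tabulate(c(p$i, p$j), nbins = n)

  qlm <- matrix(NA_complex_, n, l + 1L)
  if (nrow(p)) {
    d <- as.matrix(p[, c("dx", "dy", "dz")])
    u <- d / p$r
    centers <- c(p$i, p$j)
    dirs <- rbind(u, -u)  # bond i->j seen from i, and j->i seen from j
    Y <- spherical_harmonics(l, dirs)
    sre <- rowsum(Re(Y), centers)
    sim <- rowsum(Im(Y), centers)
    rows <- as.integer(rownames(sre))  # rowsum drops empty groups
    qlm[rows, ] <- (sre + 1i * sim) / nb[rows]
  }
  q <- ql_from_qlm(qlm, l)

  structure(
    list(l = l, q = q, qlm = qlm, n_neighbors = nb, variant = "q",
         graph_info = graph_fingerprint(graph)),
    class = "order_parameter_set"
  )
}

# rotationally invariant modulus; m < 0 contributions enter via symmetry
ql_from_qlm <- function(qlm, l) {
  mod2 <- Mod(qlm)^2
  w <- c(1, rep(2, l))
  s <- as.numeric(mod2 %*% w)
  sqrt(4 * pi / (2 * l + 1) * s)
}

#' Locally-averaged Steinhardt order parameter
#'
#' Averages the complex coefficient vectors q_lm over the closed
#' neighbourhood `{i} union N(i)` before taking the rotationally invariant
#' modulus.  The averaging sharpens the separation between ice-like and
#' liquid-like environments; it is not idempotent (averaging twice keeps
#' widening the stencil), so results carry a `variant` tag.
#'
#' @param order_set A [steinhardt_q()] result.
#' @param graph The same neighbour graph the order set was computed on; a
#'   mismatched graph is an error.
#' @return An `order_parameter_set` with `variant = "qbar"`.
#' @export
local_average_q <- function(order_set, graph) {
  stopifnot(inherits(order_set, "order_parameter_set"),
            inherits(graph, "neighbor_graph"))
  if (!isTRUE(all.equal(order_set$graph_info, graph_fingerprint(graph)))) {
    stop("order set was not computed on this neighbour graph")
  }
  n <- nrow(order_set$qlm)
  l <- order_set$l
  p <- graph$pairs
  qlm <- order_set$qlm
  acc <- qlm
  acc[is.na(acc)] <- 0 + 0i
  cnt <- rep(1L, n)
  cnt[order_set$n_neighbors == 0L] <- 0L
  if (nrow(p)) {
    centers <- c(p$i, p$j)
    sources <- c(p$j, p$i)
    # every neighbour has >= 1 neighbour itself (the edge is mutual), so its
    # coefficients are always defined
    add_re <- rowsum(Re(qlm[sources, , drop = FALSE]), centers)
    add_im <- rowsum(Im(qlm[sources, , drop = FALSE]), centers)
    rows <- as.integer(rownames(add_re))
    acc[rows, ] <- acc[rows, , drop = FALSE] + add_re + 1i * add_im
    cnt <- cnt + tabulate(centers, nbins = n)
  }
  qbar <- acc / cnt
  qbar[cnt == 0L, ] <- NA_complex_
  q <- ql_from_qlm(qbar, l)

  structure(
    list(l = l, q = q, qlm = qbar, n_neighbors = order_set$n_neighbors,
         variant = "qbar", graph_info = order_set$graph_info),
    class = "order_parameter_set"
  )
}

#' Threshold an order-parameter set into ice-like labels
#'
#' @param order_set An `order_parameter_set` (plain or locally averaged).
#' @param threshold Threshold in (0, 1); atoms with `q >= threshold` are
#'   labelled ice-like.  Undefined (`NA`) values are labelled liquid.
#' @param min_neighbors Minimum coordination required for an ice label
#'   (default 4, a complete first shell).  An under-coordinated molecule
#'   cannot be part of an ice lattice, and with one or two bonds the
#'   Steinhardt modulus is trivially large (a single bond gives q_l = 1 for
#'   every l by the spherical-harmonic addition theorem), so coordination
#'   must gate the threshold.
#' @return An object of class `ice_labels`: logical `ice_like`, the
#'   `threshold`, `min_neighbors` and the order-parameter `variant` used.
#' @export
classify_ice <- function(order_set, threshold, min_neighbors = 4L) {
  stopifnot(inherits(order_set, "order_parameter_set"))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("'threshold' must lie in (0, 1)")
  }
  lab <- order_set$q >= threshold & order_set$n_neighbors >= min_neighbors
  lab[is.na(lab)] <- FALSE
  structure(
    list(ice_like = lab, threshold = threshold,
         min_neighbors = as.integer(min_neighbors),
         variant = order_set$variant,
         n_undefined = sum(is.na(order_set$q))),
    class = "ice_labels"
  )
}

#' Calibrate an ice/liquid classification threshold
#'
#' Places the threshold midway between the 1st percentile of the ice
#' fixture's order-parameter distribution and the 99th percentile of the
#' liquid fixture's.  If the two percentiles overlap the distributions are
#' not separable at that confidence and an error reports both values.
#'
#' @param ice_fixture,liquid_fixture `order_parameter_set` objects (or bare
#'   numeric vectors of q values) computed on known-ice and known-liquid
#'   fixtures with the same `l`, cutoff and variant.
#' @param min_neighbors Order-set entries below this coordination are
#'   excluded before taking percentiles, mirroring the gate applied by
#'   [classify_ice()].
#' @return The calibrated threshold (numeric scalar).
#' @export
calibrate_threshold <- function(ice_fixture, liquid_fixture,
                                min_neighbors = 4L) {
  get_q <- function(x) {
    if (inherits(x, "order_parameter_set")) {
      x$q[x$n_neighbors >= min_neighbors]
    } else {
      as.numeric(x)
    }
  }
  qi <- get_q(ice_fixture); ql <- get_q(liquid_fixture)
  lo <- as.numeric(stats::quantile(qi, 0.01, na.rm = TRUE))
  hi <- as.numeric(stats::quantile(ql, 0.99, na.rm = TRUE))
  if (hi >= lo) {
    stop(sprintf(
      "distributions overlap: ice 1st percentile %.4f <= liquid 99th percentile %.4f",
      lo, hi
    ))
  }
  (lo + hi) / 2
}
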