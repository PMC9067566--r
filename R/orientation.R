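# Orientation analyses: monolayer tilt, water / hydroxyl dipole angles,
# and interfacial-water selection.
#
# All angles are measured per leaflet against a reference normal so the two
# equivalent interfaces of the slab superpose onto one distribution:
#   - tilt: the molecular axis (tail C25 -> head C3) against the leaflet's
#     water-ward normal, so an upright molecule has tilt 0;
#   - dipoles: against the outward normal of the nearer interface (pointing
#     from the water bulk toward the monolayer).

#' Probability density over orientation angles
#'
#' Histogram density over \[0, 180\] degrees, normalised so the integral
#' over the full range is one.  The default mode reports the raw per-degree
#' density; `jacobian = "sin"` divides by the solid-angle factor sin(theta)
#' (and renormalises), under which isotropically distributed vectors give a
#' flat density.
#'
#' @param angles_deg Angles in degrees, within \[0, 180\].
#' @param bin_width Bin width in degrees.
#' @param jacobian `"none"` (per-degree density, default) or `"sin"`.
#' @param kind Tag describing the vector analysed (e.g. `"axis_tilt"`,
#'   `"water_dipole"`, `"chol_oh"`).
#' @return An object of class `orientation_distribution`: `centers`,
#'   `density` (per degree), `bin_width`, `kind`, `jacobian`, `n`.
#' @export
orientation_distribution <- function(angles_deg, bin_width = 2,
                                     jacobian = c("none", "sin"),
                                     kind = "generic") {
  jacobian <- match.arg(jacobian)
  angles_deg <- angles_deg[is.finite(angles_deg)]
  if (!length(angles_deg)) stop("no finite angles supplied")
  if (any(angles_deg < -1e-9 | angles_deg > 180 + 1e-9)) {
    stop("angles must lie in [0, 180] degrees")
  }
  edges <- seq(0, 180, by = bin_width)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  counts <- graphics::hist(pmin(pmax(angles_deg, 0), 180), breaks = edges,
                           plot = FALSE, right = FALSE)$counts
  # the final (right-open) bin loses exact 180s; put them back
  counts[length(counts)] <- counts[length(counts)] + sum(angles_deg == 180)
  centers <- edges[-length(edges)] + diff(edges) / 2
  w <- counts
  if (jacobian == "sin") {
    s <- sin(centers * pi / 180)
    s <- pmax(s, sin(bin_width / 2 * pi / 180))  # guard the poles
    w <- counts / s
  }
  widths <- diff(edges)
  dens <- w / sum(w * widths)
  structure(
    list(centers = centers, density = dens, bin_width = bin_width,
         kind = kind, jacobian = jacobian, n = length(angles_deg)),
    class = "orientation_distribution"
  )
}

#' Mode of an orientation distribution
#' @param dist An [orientation_distribution()].
#' @return The bin-centre angle (degrees) of the highest density bin.
#' @export
peak_angle <- function(dist) {
  stopifnot(inherits(dist, "orientation_distribution"))
  dist$centers[which.max(dist$density)]
}

slab_midplane <- function(config, topology) {
  if (nrow(topology$water)) mean(config$coords[topology$water$O, 3])
  else config$box[3] / 2
}

angle_to_normal <- function(vec, normal_z) {
  nv <- sqrt(rowSums(vec^2))
  if (any(nv < 1e-9)) {
    stop(sprintf("zero-length vector for molecule(s): %s",
                 paste(which(nv < 1e-9), collapse = ", ")))
  }
  ct <- (vec[, 3] * normal_z) / nv
  acos(pmin(pmax(ct, -1), 1)) * 180 / pi
}

#' Monolayer tilt angles
#'
#' The tilt of each surrogate cholesterol is the angle between its
#' molecular axis (tail C25 to head C3) and the water-ward normal of its
#' leaflet (-z for the upper leaflet, +z for the lower), so an upright
#' molecule scores 0 degrees, an in-plane one 90 degrees, and the two
#' leaflets superpose.
#'
#' @param config A [configuration].
#' @param topology Matching [infer_topology()]; computed when `NULL`.
#' @param midplane Slab midplane z; defaults to the mean water-oxygen z.
#' @param bin_width Histogram bin width (degrees).
#' @return List with `theta_z` (per-molecule angles, degrees, named by
#'   molecule id) and `distribution` (an [orientation_distribution()]).
#' @export
tilt_angles <- function(config, topology = NULL, midplane = NULL,
                        bin_width = 2) {
  if (is.null(topology)) topology <- infer_topology(config)
  ch <- topology$chol
  if (!nrow(ch)) stop("no surrogate cholesterol molecules in the topology")
  if (is.null(midplane)) midplane <- slab_midplane(config, topology)
  axis <- config$coords[ch$axis_head, , drop = FALSE] -
    config$coords[ch$axis_tail, , drop = FALSE]
  upper <- config$coords[ch$axis_head, 3] > midplane
  normal_z <- ifelse(upper, -1, 1)  # water-ward
  th <- angle_to_normal(axis, normal_z)
  names(th) <- ch$mol
  list(theta_z = th,
       distribution = orientation_distribution(th, bin_width = bin_width,
                                               kind = "axis_tilt"))
}

#' Dipole orientation angles
#'
#' Water dipole: oxygen to the midpoint of the two hydrogens (the H-O-H
#' bisector).  Cholesterol hydroxyl: O1 to H1.  Angles are measured against
#' the outward normal of the nearer interface (+z above the midplane, -z
#' below), degrees in \[0, 180\].
#'
#' @param config A [configuration].
#' @param topology Matching [infer_topology()]; computed when `NULL`.
#' @param subset `"water"` or `"chol_oh"`.
#' @param molecule_ids Optional molecule ids to restrict to (e.g. the
#'   interfacial waters from [select_interfacial_water()]).
#' @param midplane Slab midplane z; defaults to the mean water-oxygen z.
#' @param bin_width Histogram bin width (degrees).
#' @param jacobian Passed to [orientation_distribution()].
#' @return List with `theta_z` (per-molecule angles, named by molecule id)
#'   and `distribution`.
#' @export
dipole_angles <- function(config, topology = NULL,
                          subset = c("water", "chol_oh"),
                          molecule_ids = NULL, midplane = NULL,
                          bin_width = 2, jacobian = "none") {
  subset <- match.arg(subset)
  if (is.null(topology)) topology <- infer_topology(config)
  if (is.null(midplane)) midplane <- slab_midplane(config, topology)
  per <- config$periodic
  box <- config$box
  if (subset == "water") {
    w <- topology$water
    if (!nrow(w)) stop("no water molecules in the topology")
    if (!is.null(molecule_ids)) w <- w[w$mol %in% molecule_ids, , drop = FALSE]
    if (!nrow(w)) stop("no water molecules left after subsetting")
    o <- config$coords[w$O, , drop = FALSE]
    h1 <- o + minimum_image(config$coords[w$H1, , drop = FALSE] - o, box, per)
    h2 <- o + minimum_image(config$coords[w$H2, , drop = FALSE] - o, box, per)
    vec <- (h1 + h2) / 2 - o
    ref_z <- o[, 3]
    mols <- w$mol
    kind <- "water_dipole"
  } else {
    ch <- topology$chol
    if (!nrow(ch)) stop("no surrogate cholesterol molecules in the topology")
    if (!is.null(molecule_ids)) ch <- ch[ch$mol %in% molecule_ids, , drop = FALSE]
    o <- config$coords[ch$oh_O, , drop = FALSE]
    vec <- minimum_image(config$coords[ch$oh_H, , drop = FALSE] - o, box, per)
    ref_z <- o[, 3]
    mols <- ch$mol
    kind <- "chol_oh"
  }
  normal_z <- ifelse(ref_z > midplane, 1, -1)  # outward
  th <- angle_to_normal(vec, normal_z)
  names(th) <- mols
  list(theta_z = th,
       distribution = orientation_distribution(th, bin_width = bin_width,
                                               jacobian = jacobian,
                                               kind = kind))
}

#' Select interfacial water molecules
#'
#' A water is interfacial when its oxygen lies within `cutoff` (inclusive)
#' of any oxygen belonging to a surrogate cholesterol, under minimum image
#' along the periodic axes.  The default 7 angstrom matches the second peak
#' of the water density profile near cholesterol surfaces; selections are
#' robust for cutoffs in roughly 5-10 angstrom.
#'
#' @param config A [configuration].
#' @param topology Matching [infer_topology()]; computed when `NULL`.
#' @param cutoff Distance cutoff (angstrom, > 0).
#' @return Integer vector of interfacial water molecule ids.
#' @export
select_interfacial_water <- function(config, topology = NULL, cutoff = 7) {
  if (cutoff <= 0) stop("'cutoff' must be positive")
  if (is.null(topology)) topology <- infer_topology(config)
  if (!nrow(topology$chol)) {
    stop("no surrogate cholesterol molecules in the topology")
  }
  if (!nrow(topology$water)) return(integer(0))
  wo <- config$coords[topology$water$O, , drop = FALSE]
  co <- config$coords[topology$chol$oh_O, , drop = FALSE]
  sel <- rep(FALSE, nrow(wo))
  for (k in seq_len(nrow(co))) {
    d <- sweep(wo, 2L, co[k, ], "-")
    d <- minimum_image(d, config$box, config$periodic)
    sel <- sel | rowSums(d * d) <= cutoff^2
  }
  topology$water$mol[sel]
}
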