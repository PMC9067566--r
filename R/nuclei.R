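# Ice nuclei: connected clusters of ice-like molecules, their
# centre-of-mass z positions, and the normalised P(COM_z) profile.

#' Cluster ice-like molecules into nuclei
#'
#' Connected components of the neighbour graph restricted to ice-like
#' molecules.  The largest nucleus is selected; ties are broken by the
#' smallest minimum member index (deterministic and order-independent).
#'
#' @param labels An [classify_ice()] result.
#' @param graph The matching [neighbor_list()] graph.
#' @param frame_time Optional frame time (ps), carried as metadata.
#' @return An object of class `nucleus_set`: `clusters` (list of integer
#'   member-index vectors), `sizes`, `largest_index` (`NA` when no molecule
#'   is ice-like) and `frame_time`.
#' @export
cluster_nuclei <- function(labels, graph, frame_time = NA_real_) {
  stopifnot(inherits(labels, "ice_labels"), inherits(graph, "neighbor_graph"))
  if (length(labels$ice_like) != graph$n_atoms) {
    stop("labels and graph disagree on molecule count")
  }
  ice <- which(labels$ice_like)
  if (!length(ice)) {
    return(structure(list(clusters = list(), sizes = integer(0),
                          largest_index = NA_integer_,
                          frame_time = frame_time),
                     class = "nucleus_set"))
  }
  p <- graph$pairs
  keep <- p$i %in% ice & p$j %in% ice
  relabel <- integer(graph$n_atoms)
  relabel[ice] <- seq_along(ice)
  g <- igraph::make_empty_graph(n = length(ice), directed = FALSE)
  if (any(keep)) {
    g <- igraph::add_edges(g, rbind(relabel[p$i[keep]], relabel[p$j[keep]]))
  }
  comp <- igraph::components(g)
  clusters <- split(ice, comp$membership)
  clusters <- unname(lapply(clusters, sort))
  sizes <- lengths(clusters)
  mx <- max(sizes)
  cand <- which(sizes == mx)
  largest <- cand[which.min(vapply(clusters[cand], min, numeric(1)))]
  structure(list(clusters = clusters, sizes = sizes, largest_index = largest,
                 frame_time = frame_time),
            class = "nucleus_set")
}

#' @export
print.nucleus_set <- function(x, ...) {
  cat(sprintf("<nucleus_set> %d clusters, largest size %s\n",
              length(x$clusters),
              if (is.na(x$largest_index)) "NA" else x$sizes[x$largest_index]))
  invisible(x)
}

#' Centre of mass of a nucleus
#'
#' Unweighted mean of the member positions after minimum-image unwrapping
#' relative to the first member along the periodic axes (so clusters
#' straddling the xy boundary are handled correctly); z is taken raw on the
#' non-periodic slab axis.
#'
#' @param members Integer member indices (atoms of the oxygen
#'   configuration), or a `nucleus_set` whose largest cluster is used.
#' @param config The oxygen [configuration] the members index into.
#' @return `nucleus_com()` returns the length-3 centre of mass (angstrom);
#'   `nucleus_com_z()` its z component.
#' @export
nucleus_com <- function(members, config) {
  if (inherits(members, "nucleus_set")) {
    if (is.na(members$largest_index)) stop("nucleus set is empty")
    members <- members$clusters[[members$largest_index]]
  }
  if (!length(members)) stop("cannot compute the centre of mass of an empty nucleus")
  x <- config$coords[members, , drop = FALSE]
  ref <- x[1L, ]
  d <- sweep(x, 2L, ref, "-")
  d <- minimum_image(d, config$box, config$periodic)
  ref + colMeans(d)
}

#' @rdname nucleus_com
#' @export
nucleus_com_z <- function(members, config) {
  nucleus_com(members, config)[3L]
}

#' Normalised profile of largest-nucleus COM z positions
#'
#' Histograms a stream of COM z values, optionally folding the two slab
#' interfaces onto each other about the midplane, normalises so the mean
#' density over the baseline (bulk) window equals one, and aligns the peak
#' bin inside the interface window to zero.
#'
#' @param com_z Numeric vector of COM z values (angstrom).  When
#'   `fold = TRUE` these are replaced by their distance from `midplane`.
#' @param bin_width Histogram bin width (angstrom).
#' @param fold Fold about the slab midplane so the two equivalent
#'   interfaces superpose (default `TRUE`).
#' @param midplane Slab midplane z (required when folding).
#' @param baseline_window Length-2 window (in the profile coordinate,
#'   before alignment) whose mean density defines the bulk baseline.
#' @param interface_window Length-2 window within which the peak is located
#'   and the enhancement is measured.  Must be disjoint from the baseline
#'   window.
#' @return An object of class `com_z_profile`: bin `edges`, `centers`,
#'   `counts`, normalised `density`, `aligned_centers` (peak at zero),
#'   `offset`, the windows and bin width used, and `n` (sample count).
#' @export
com_z_profile <- function(com_z, bin_width = 0.5, fold = TRUE,
                          midplane = NULL, baseline_window, interface_window) {
  com_z <- com_z[is.finite(com_z)]
  if (!length(com_z)) stop("need at least one valid COM z value")
  if (fold) {
    if (is.null(midplane)) stop("'midplane' is required when fold = TRUE")
    com_z <- abs(com_z - midplane)
  }
  if (length(baseline_window) != 2L || length(interface_window) != 2L) {
    stop("windows must be length-2 ranges")
  }
  baseline_window <- sort(baseline_window)
  interface_window <- sort(interface_window)
  if (max(min(baseline_window[2], interface_window[2]) -
          max(baseline_window[1], interface_window[1]), 0) > 0) {
    stop("baseline and interface windows must be disjoint")
  }
  lo <- floor(min(com_z) / bin_width) * bin_width
  hi <- ceiling(max(com_z) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- graphics::hist(com_z, breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  centers <- edges[-length(edges)] + bin_width / 2
  raw <- counts / (length(com_z) * bin_width)

  in_base <- centers >= baseline_window[1] & centers <= baseline_window[2]
  if (!any(in_base) || sum(counts[in_base]) == 0L) {
    stop("no occupancy in the baseline window: cannot normalise")
  }
  dens <- raw / mean(raw[in_base])

  in_int <- centers >= interface_window[1] & centers <= interface_window[2]
  if (!any(in_int)) stop("interface window lies outside the histogram support")
  peak <- which(in_int)[which.max(dens[in_int])]
  offset <- centers[peak]

  structure(
    list(edges = edges, centers = centers, counts = counts, density = dens,
         aligned_centers = centers - offset, offset = offset,
         peak_bin = peak, baseline_window = baseline_window,
         interface_window = interface_window, bin_width = bin_width,
         fold = fold, midplane = if (fold) midplane else NA_real_,
         n = length(com_z)),
    class = "com_z_profile"
  )
}

#' Interfacial enhancement ratio of a COM-z profile
#'
#' Mean normalised density over the interface window; the bulk baseline is
#' one by construction, so a flat profile returns ~1 and a planted 10:1
#' interface:bulk trajectory returns ~10.
#'
#' @param profile A [com_z_profile()].
#' @param interface_window Optional override window (profile coordinate,
#'   pre-alignment); defaults to the profile's own.
#' @return Numeric enhancement ratio.
#' @export
interfacial_enhancement <- function(profile, interface_window = NULL) {
  stopifnot(inherits(profile, "com_z_profile"))
  w <- sort(interface_window %||% profile$interface_window)
  if (w[1] > max(profile$edges) || w[2] < min(profile$edges)) {
    stop("interface window lies outside the histogram support")
  }
  sel <- profile$centers >= w[1] & profile$centers <= w[2]
  if (!any(sel)) stop("interface window contains no bins")
  mean(profile$density[sel])
}

#' Largest-nucleus trace of a trajectory
#'
#' Runs the full per-frame pipeline: water-oxygen extraction, neighbour
#' graph, (locally averaged) Steinhardt q_l, thresholding, clustering, and
#' the COM z of the largest nucleus.
#'
#' @param traj A [trajectory].
#' @param threshold Ice classification threshold (see
#'   [calibrate_threshold()]).
#' @param cutoff O-O neighbour cutoff (angstrom).
#' @param l Spherical-harmonic order.
#' @param average Use the locally averaged variant (default `TRUE`).
#' @param method Neighbour search method.
#' @return Data frame with one row per frame: `frame`, `time`, `size`
#'   (largest-nucleus size, 0 when none) and `com_z` (`NA` when none).
#' @export
largest_nucleus_trace <- function(traj, threshold, cutoff = 3.5, l = 6L,
                                  average = TRUE, method = "brute") {
  stopifnot(inherits(traj, "trajectory"))
  nf <- length(traj$frames)
  out <- data.frame(frame = seq_len(nf), time = traj$times,
                    size = 0L, com_z = NA_real_)
  topo <- infer_topology(traj$frames[[1L]])
  for (f in seq_len(nf)) {
    res <- frame_ice_analysis(traj$frames[[f]], topology = topo,
                              threshold = threshold, cutoff = cutoff, l = l,
                              average = average, method = method)
    if (!is.na(res$nuclei$largest_index)) {
      members <- res$nuclei$clusters[[res$nuclei$largest_index]]
      out$size[f] <- length(members)
      out$com_z[f] <- nucleus_com_z(members, res$oxygens$config)
    }
  }
  out
}

#' Single-frame ice analysis
#'
#' @param config A [configuration] holding (at least) water molecules.
#' @param topology Optional precomputed [infer_topology()] result.
#' @param threshold Ice classification threshold.
#' @inheritParams largest_nucleus_trace
#' @return List with `oxygens` (the oxygen sub-configuration and molecule
#'   map), `graph`, `order` (the thresholded order-parameter set),
#'   `labels` and `nuclei`.
#' @export
frame_ice_analysis <- function(config, topology = NULL, threshold,
                               cutoff = 3.5, l = 6L, average = TRUE,
                               method = "brute") {
  ox <- water_oxygen_config(config, topology)
  graph <- neighbor_list(ox$config, cutoff = cutoff, method = method)
  ord <- steinhardt_q(ox$config, graph, l = l)
  if (average) ord <- local_average_q(ord, graph)
  labels <- classify_ice(ord, threshold)
  nuclei <- cluster_nuclei(labels, graph)
  list(oxygens = ox, graph = graph, order = ord, labels = labels,
       nuclei = nuclei)
}
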