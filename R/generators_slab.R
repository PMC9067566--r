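# Liquid slabs, surrogate monolayers and planted-nucleus trajectories.

# rigid 3-site water: O at origin, H-O-H angle 104.52 deg, r(OH) 0.9572 A,
# bisector along +z
water_template <- function() {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(
    O = c(0, 0, 0),
    H1 = r_oh * c(sin(half), 0, cos(half)),
    H2 = r_oh * c(-sin(half), 0, cos(half))
  )
}

# randomly oriented rigid waters at the given oxygen positions
place_waters <- function(o_pos, box) {
  n <- nrow(o_pos)
  tmpl <- water_template()
  coords <- matrix(NA_real_, 3L * n, 3L)
  for (k in seq_len(n)) {
    R <- random_rotation()
    block <- tmpl %*% t(R)
    rows <- (3L * (k - 1L) + 1L):(3L * k)
    coords[rows, ] <- sweep(block, 2L, o_pos[k, ], "+")
  }
  configuration(
    rep(c("OW", "HW1", "HW2"), n), coords, box,
    molecule_ids = rep(seq_len(n), each = 3L),
    periodic = c(TRUE, TRUE, FALSE)
  )
}

# random sequential insertion of points with a pairwise minimum distance,
# using a coarse cell grid for the overlap query
rsa_insert <- function(n, box, periodic, min_dist, z_range, max_attempts) {
  if (n == 0L) return(matrix(numeric(0), 0L, 3L))
  cell <- max(min_dist, 1e-6)
  nc <- pmax(1L, as.integer(floor(c(box[1], box[2], z_range[2] - z_range[1]) / cell)))
  grid <- new.env(hash = TRUE)
  key_of <- function(p) {
    ci <- pmin(pmax(floor(c(
      p[1] / box[1] * nc[1], p[2] / box[2] * nc[2],
      (p[3] - z_range[1]) / max(z_range[2] - z_range[1], 1e-9) * nc[3]
    )), 0), nc - 1L)
    ci
  }
  pts <- matrix(NA_real_, n, 3L)
  placed <- 0L
  attempts <- 0L
  while (placed < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(
        "packing infeasible: placed %d of %d points after %d attempts (min_dist %.2f)",
        placed, n, max_attempts, min_dist
      ))
    }
    cand <- c(stats::runif(1) * box[1], stats::runif(1) * box[2],
              z_range[1] + stats::runif(1) * (z_range[2] - z_range[1]))
    ci <- key_of(cand)
    ok <- TRUE
    for (ox in -1:1) for (oy in -1:1) for (oz in -1:1) {
      cc <- ci + c(ox, oy, oz)
      for (k in 1:2) if (periodic[k]) cc[k] <- ((cc[k] %% nc[k]) + nc[k]) %% nc[k]
      if (any(cc < 0) || any(cc >= nc)) next
      occ <- grid[[paste(cc, collapse = ",")]]
      if (is.null(occ)) next
      d <- pts[occ, , drop = FALSE] -
        matrix(cand, length(occ), 3L, byrow = TRUE)
      d <- minimum_image(d, box, periodic)
      if (any(rowSums(d * d) < min_dist^2)) { ok <- FALSE; break }
    }
    if (!ok) next
    placed <- placed + 1L
    pts[placed, ] <- cand
    key <- paste(ci, collapse = ",")
    grid[[key]] <- c(grid[[key]], placed)
  }
  pts
}

#' Build a disordered liquid water slab
#'
#' Random sequential insertion of rigid, randomly oriented waters with a
#' pairwise O-O minimum distance, periodic in xy only.
#'
#' @param n_molecules Number of waters (0 gives an empty configuration).
#' @param box Length-3 box edges (angstrom).
#' @param min_dist Minimum O-O distance (angstrom).
#' @param seed RNG seed.
#' @param z_range Length-2 range of oxygen z coordinates; defaults to the
#'   full box so callers can carve out a slab plus vacuum.
#' @param max_attempts Insertion retry budget before declaring the packing
#'   infeasible.
#' @return A slab [configuration] (periodic x, y only).
#' @export
build_liquid_slab <- function(n_molecules, box, min_dist = 2.5, seed = 1L,
                              z_range = c(0, box[3]),
                              max_attempts = 400L * max(n_molecules, 1L)) {
  if (n_molecules < 0L) stop("'n_molecules' must be >= 0")
  with_seed(seed, {
    o_pos <- rsa_insert(n_molecules, box, c(TRUE, TRUE, FALSE), min_dist,
                        z_range, max_attempts)
    if (n_molecules == 0L) {
      configuration(character(0), matrix(numeric(0), 0L, 3L), box,
                    molecule_ids = integer(0), periodic = c(TRUE, TRUE, FALSE))
    } else {
      place_waters(o_pos, box)
    }
  })
}

#' Build a surrogate cholesterol monolayer system
#'
#' Places two leaflets of rigid two-site rods (tail atom `C25`, head atom
#' `C3`, hydroxyl `O1`-`H1` pointing toward the water) above and below a
#' liquid water slab.  The in-plane box edge is
#' `sqrt(n_chl * S_A_per_mol)`; the axis polar angle of each rod is drawn
#' from a wrapped-Gaussian cone (a von Mises-Fisher-like distribution)
#' about the prescribed mean tilt, with concentration `tilt_kappa`
#' (`Inf` gives exactly the mean tilt; the angular spread is
#' `1/sqrt(kappa)` radians).  Tilt is defined against each leaflet's
#' water-ward normal, so an upright molecule has tilt 0 and both leaflets
#' superpose.
#'
#' @param n_chl Surrogate molecules per leaflet.
#' @param S_A_per_mol Surface area per molecule (angstrom^2).
#' @param tilt_mean Mean tilt angle, degrees in \[0, 90\].
#' @param tilt_kappa Concentration of the tilt distribution.
#' @param seed RNG seed.
#' @param axis_length Tail-to-head rod length (angstrom).
#' @param head_gap Gap between the water surface and the head carbon
#'   (angstrom).
#' @param water List of water-slab parameters: `thickness` (angstrom),
#'   `density` (molecules per angstrom^3), `min_dist` (angstrom).
#' @param box_z Total box height including vacuum (angstrom).
#' @param min_xy_dist Minimum in-plane distance between surrogate heads.
#' @return List with `configuration`, `topology`, and `tilt_true` (the
#'   planted per-molecule tilt angles, degrees; ground truth for recovery
#'   tests).
#' @export
build_monolayer_slab <- function(n_chl = 64L, S_A_per_mol = 70,
                                 tilt_mean = 30, tilt_kappa = 100,
                                 seed = 1L, axis_length = 17,
                                 head_gap = 3,
                                 water = list(thickness = 40,
                                              density = 0.0265,
                                              min_dist = 2.5),
                                 box_z = 200, min_xy_dist = 5) {
  if (n_chl < 1L) stop("'n_chl' must be >= 1")
  if (S_A_per_mol <= 0) stop("'S_A_per_mol' must be positive")
  if (tilt_mean < 0 || tilt_mean > 90) {
    stop("'tilt_mean' must lie in [0, 90] degrees")
  }
  L <- sqrt(n_chl * S_A_per_mol)
  box <- c(L, L, box_z)
  thickness <- water$thickness %||% 40
  density <- water$density %||% 0.0265
  min_dist <- water$min_dist %||% 2.5
  n_water <- round(density * L^2 * thickness)
  z_mid <- box_z / 2
  z_lo <- z_mid - thickness / 2
  z_hi <- z_mid + thickness / 2

  with_seed(seed, {
    o_pos <- rsa_insert(n_water, box, c(TRUE, TRUE, FALSE), min_dist,
                        c(z_lo, z_hi), 400L * max(n_water, 1L))
    wat <- place_waters(o_pos, box)

    # jittered grid of head positions per leaflet, min_xy_dist enforced by
    # bounding the jitter
    n_side <- ceiling(sqrt(n_chl))
    spacing <- L / n_side
    if (spacing < min_xy_dist) {
      stop(sprintf("S_A_per_mol too small to honour the %.1f A in-plane spacing",
                   min_xy_dist))
    }
    jit <- max(0, (spacing - min_xy_dist) / 2)
    grid_xy <- as.matrix(expand.grid(
      x = (seq_len(n_side) - 0.5) * spacing,
      y = (seq_len(n_side) - 0.5) * spacing
    ))[seq_len(n_chl), , drop = FALSE]

    sd_deg <- if (is.infinite(tilt_kappa)) 0 else (180 / pi) / sqrt(tilt_kappa)
    build_leaflet <- function(side) {  # +1 upper, -1 lower
      xy <- grid_xy + matrix(stats::runif(2L * n_chl, -jit, jit), n_chl, 2L)
      theta <- if (sd_deg == 0) rep(tilt_mean, n_chl) else
        stats::rnorm(n_chl, tilt_mean, sd_deg)
      theta <- abs(theta)
      theta <- ifelse(theta > 90, 180 - theta, theta)
      phi <- stats::runif(n_chl, 0, 2 * pi)
      waterward <- c(0, 0, -side)
      th <- theta * pi / 180
      # axis direction C25 -> C3, tilted theta away from the water-ward normal
      dirs <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), -side * cos(th))
      head_z <- if (side > 0) z_hi + head_gap else z_lo - head_gap
      c3 <- cbind(xy, rep(head_z, n_chl))
      c25 <- c3 - axis_length * dirs
      o1 <- c3 + 1.43 * dirs
      h1 <- o1 + 0.96 * dirs
      list(c3 = c3, c25 = c25, o1 = o1, h1 = h1, theta = theta)
    }
    up <- build_leaflet(+1)
    dn <- build_leaflet(-1)

    n_tot_chl <- 2L * n_chl
    coords <- rbind(wat$coords,
                    do.call(rbind, lapply(seq_len(n_chl), function(k) {
                      rbind(up$c3[k, ], up$c25[k, ], up$o1[k, ], up$h1[k, ])
                    })),
                    do.call(rbind, lapply(seq_len(n_chl), function(k) {
                      rbind(dn$c3[k, ], dn$c25[k, ], dn$o1[k, ], dn$h1[k, ])
                    })))
    names_chl <- rep(c("C3", "C25", "O1", "H1"), n_tot_chl)
    mol_chl <- rep(n_water + seq_len(n_tot_chl), each = 4L)
    config <- configuration(
      c(wat$atom_names, names_chl), coords, box,
      molecule_ids = c(wat$molecule_ids, mol_chl),
      periodic = c(TRUE, TRUE, FALSE)
    )
    list(
      configuration = config,
      topology = infer_topology(config),
      tilt_true = c(up$theta, dn$theta)
    )
  })
}

#' Plant ice nuclei into a liquid slab
#'
#' Builds a trajectory in which every frame is the base slab plus one
#' ice-like cluster cut from an ideal Ic lattice, randomly rotated and
#' embedded at a z position drawn from a prescribed density.  Overlapping
#' base waters are removed; to keep the atom count identical across frames
#' (a trajectory invariant), every frame removes the same total number of
#' waters, padding with randomly chosen far-from-nucleus waters.  The
#' planted ground truth is returned alongside the data.
#'
#' @param base_slab A liquid-slab [configuration] (waters only).
#' @param nucleus_size Molecules per planted nucleus.
#' @param z_density Function of z (angstrom) giving the (unnormalised)
#'   placement density of the nucleus centre.
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @param z_range Support of the placement density; defaults to the base
#'   slab's oxygen z range.
#' @param min_dist Base waters closer than this to any nucleus oxygen are
#'   removed (angstrom).
#' @param dt Frame spacing (ps).
#' @return List with `trajectory` and `truth` (data frame: `frame`, `time`,
#'   `z_planted`, `com_z_planted`, `n_planted`) plus `planted_ids` (per-frame
#'   molecule ids of nucleus members).
#' @export
plant_nuclei_trajectory <- function(base_slab, nucleus_size = 32L, z_density,
                                    n_frames = 100L, seed = 1L,
                                    z_range = NULL, min_dist = 2.4, dt = 1) {
  stopifnot(inherits(base_slab, "configuration"))
  topo <- infer_topology(base_slab)
  o_idx <- topo$water$O
  if (!length(o_idx)) stop("base slab contains no waters")
  box <- base_slab$box
  if (is.null(z_range)) z_range <- range(base_slab$coords[o_idx, 3])

  # nucleus template: compact cluster carved from ideal cubic ice
  latt <- build_ice_lattice("Ic", c(3L, 3L, 3L), protons = FALSE, seed = 1L)
  ctr <- latt$box / 2
  d2 <- rowSums(sweep(latt$coords, 2L, ctr, "-")^2)
  pick <- order(d2)[seq_len(nucleus_size)]
  template <- sweep(latt$coords[pick, , drop = FALSE], 2L,
                    colMeans(latt$coords[pick, , drop = FALSE]), "-")
  tmpl_radius <- sqrt(max(rowSums(template^2)))
  if (2 * tmpl_radius > diff(z_range) + 10) {
    stop("nucleus larger than the slab")
  }

  zg <- seq(z_range[1], z_range[2], length.out = 512L)
  w <- z_density(zg)
  if (any(!is.finite(w)) || any(w < 0) || sum(w) <= 0) {
    stop("'z_density' must be non-negative with positive mass on the slab")
  }

  base_o <- base_slab$coords[o_idx, , drop = FALSE]

  with_seed(seed, {
    placements <- vector("list", n_frames)
    removed <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      zc <- sample(zg, 1L, prob = w) + stats::runif(1, -0.5, 0.5) * (zg[2] - zg[1])
      cen <- c(stats::runif(1) * box[1], stats::runif(1) * box[2], zc)
      R <- random_rotation()
      nuc <- sweep(template %*% t(R), 2L, cen, "+")
      # base waters overlapping the nucleus
      kill <- integer(0)
      for (k in seq_len(nrow(nuc))) {
        d <- sweep(base_o, 2L, nuc[k, ], "-")
        d <- minimum_image(d, box, base_slab$periodic)
        kill <- c(kill, which(rowSums(d * d) < min_dist^2))
      }
      placements[[f]] <- list(nuc = nuc, z = zc)
      removed[[f]] <- unique(kill)
    }
    k_max <- max(vapply(removed, length, integer(1)))

    frames <- vector("list", n_frames)
    planted_ids <- vector("list", n_frames)
    truth <- data.frame(frame = seq_len(n_frames),
                        time = (seq_len(n_frames) - 1) * dt,
                        z_planted = NA_real_, com_z_planted = NA_real_,
                        n_planted = nucleus_size)
    for (f in seq_len(n_frames)) {
      kill <- removed[[f]]
      extra_needed <- k_max - length(kill)
      if (extra_needed > 0L) {
        # pad with far-from-nucleus waters so atom counts match
        far <- setdiff(seq_len(nrow(base_o)), kill)
        d <- sweep(base_o[far, , drop = FALSE], 2L, placements[[f]]$nuc[1L, ], "-")
        d <- minimum_image(d, box, base_slab$periodic)
        far <- far[rowSums(d * d) > (2 * min_dist)^2]
        kill <- c(kill, sample(far, extra_needed))
      }
      wr <- topo$water[-kill, , drop = FALSE]
      keep_atoms <- sort(c(wr$O, wr$H1, wr$H2))
      kept <- subset_configuration(base_slab, keep_atoms)
      nuc_cfg <- place_waters(placements[[f]]$nuc, box)
      n_kept_mol <- nrow(wr)
      frames[[f]] <- configuration(
        c(kept$atom_names, nuc_cfg$atom_names),
        rbind(kept$coords, nuc_cfg$coords),
        box,
        molecule_ids = c(rep(seq_len(n_kept_mol), each = 3L),
                         n_kept_mol + nuc_cfg$molecule_ids),
        periodic = base_slab$periodic
      )
      planted_ids[[f]] <- n_kept_mol + seq_len(nucleus_size)
      truth$z_planted[f] <- placements[[f]]$z
      truth$com_z_planted[f] <- mean(placements[[f]]$nuc[, 3])
    }
    list(
      trajectory = trajectory(frames, times = (seq_len(n_frames) - 1) * dt),
      truth = truth,
      planted_ids = planted_ids
    )
  })
}
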