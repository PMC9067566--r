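# Ideal ice oxygen lattices.
#
# Both polytypes are built on an ideal O-O nearest-neighbour distance
# r_oo (default 2.75 angstrom, standard ice geometry):
#   Ic: diamond-cubic conventional cell, a = 4 r_oo / sqrt(3), 8 oxygens.
#   Ih: lonsdaleite-type lattice expressed in the orthohexagonal cell
#       (a, sqrt(3) a, c) with a = r_oo sqrt(8/3), c = a sqrt(8/3),
#       8 oxygens (two hexagonal cells).

ice_unit_cell <- function(polytype, r_oo) {
  if (polytype == "Ic") {
    a <- 4 * r_oo / sqrt(3)
    frac <- rbind(
      c(0, 0, 0), c(0, .5, .5), c(.5, 0, .5), c(.5, .5, 0),
      c(.25, .25, .25), c(.25, .75, .75), c(.75, .25, .75), c(.75, .75, .25)
    )
    return(list(cell = c(a, a, a), pos = frac %*% diag(c(a, a, a))))
  }
  # Ih: wurtzite-type oxygen sublattice mapped into the orthorhombic cell
  a <- r_oo * sqrt(8 / 3)
  c_ax <- a * sqrt(8 / 3)
  cell <- c(a, a * sqrt(3), c_ax)
  a1 <- c(a, 0, 0); a2 <- c(-a / 2, a * sqrt(3) / 2, 0)
  basis <- rbind(
    c(1 / 3, 2 / 3, 0), c(2 / 3, 1 / 3, 1 / 2),
    c(1 / 3, 2 / 3, 3 / 8), c(2 / 3, 1 / 3, 7 / 8)
  )
  pts <- list()
  for (i in -2:3) for (j in -2:3) {
    for (b in seq_len(nrow(basis))) {
      p <- (basis[b, 1] + i) * a1 + (basis[b, 2] + j) * a2 +
        c(0, 0, basis[b, 3] * c_ax)
      pts[[length(pts) + 1L]] <- p %% cell
    }
  }
  pts <- do.call(rbind, pts)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts) - 1L)) {
    if (!keep[i]) next
    d <- pts[(i + 1L):nrow(pts), , drop = FALSE] -
      matrix(pts[i, ], nrow(pts) - i, 3L, byrow = TRUE)
    d <- minimum_image(d, cell, c(TRUE, TRUE, TRUE))
    dup <- which(rowSums(d * d) < 1e-10)
    keep[i + dup] <- FALSE
  }
  pos <- pts[keep, , drop = FALSE]
  stopifnot(nrow(pos) == 8L)
  list(cell = cell, pos = pos)
}

#' Build an ideal ice lattice
#'
#' Generates the oxygen sublattice of cubic (`Ic`) or hexagonal (`Ih`) ice
#' under full 3D periodicity, optionally adds Gaussian displacement noise,
#' and optionally decorates the lattice with two hydrogens per oxygen
#' satisfying the ice rules (every O-O contact carries exactly one H),
#' using randomised edge orientation with repair passes.
#'
#' @param polytype `"Ih"` or `"Ic"`.
#' @param n_cells Three positive integers: unit-cell repeats per axis.
#' @param r_oo Ideal O-O nearest-neighbour distance (angstrom).
#' @param noise_sigma Standard deviation of isotropic Gaussian displacement
#'   noise (angstrom).
#' @param seed RNG seed; the generator is a pure function of it.
#' @param protons If `TRUE`, add two hydrogens per oxygen under the ice
#'   rules.  Fails with an error if the noise has destroyed the 4-regular
#'   O-O contact graph.
#' @return A fully periodic [configuration]; oxygens only (`OW`, one
#'   molecule per oxygen) or full waters (`OW`/`HW1`/`HW2`) when
#'   `protons = TRUE`.  Attributes `polytype`, `n_cells`, `cell` (unit-cell
#'   edges) and `r_oo` record the construction.
#' @export
build_ice_lattice <- function(polytype = c("Ih", "Ic"), n_cells = c(2L, 2L, 2L),
                              r_oo = 2.75, noise_sigma = 0, seed = 1L,
                              protons = FALSE) {
  polytype <- match.arg(polytype)
  n_cells <- as.integer(n_cells)
  if (length(n_cells) != 3L || any(n_cells < 1L)) {
    stop("'n_cells' must be three integers >= 1")
  }
  if (r_oo <= 0) stop("'r_oo' must be positive")
  unit <- ice_unit_cell(polytype, r_oo)
  box <- unit$cell * n_cells

  shifts <- as.matrix(expand.grid(
    x = seq_len(n_cells[1]) - 1L,
    y = seq_len(n_cells[2]) - 1L,
    z = seq_len(n_cells[3]) - 1L
  )) %*% diag(unit$cell)
  pos <- do.call(rbind, lapply(seq_len(nrow(shifts)), function(s) {
    sweep(unit$pos, 2L, shifts[s, ], "+")
  }))

  config <- with_seed(seed, {
    if (noise_sigma > 0) {
      pos <- pos + matrix(stats::rnorm(length(pos), sd = noise_sigma),
                          nrow(pos), 3L)
      pos <- wrap_coords(pos, box)
    }
    if (!protons) {
      configuration(rep("OW", nrow(pos)), pos, box,
                    molecule_ids = seq_len(nrow(pos)),
                    periodic = c(TRUE, TRUE, TRUE))
    } else {
      decorate_protons(pos, box, r_oo)
    }
  })
  attr(config, "polytype") <- polytype
  attr(config, "n_cells") <- n_cells
  attr(config, "cell") <- unit$cell
  attr(config, "r_oo") <- r_oo
  config
}

# Ice-rule proton assignment: orient every O-O contact (the donor carries
# the H), then repair until every oxygen donates exactly twice.
decorate_protons <- function(pos, box, r_oo, r_oh = 0.9572,
                             max_sweeps = 200L, max_restarts = 10L) {
  o_config <- configuration(rep("OW", nrow(pos)), pos, box,
                            molecule_ids = seq_len(nrow(pos)),
                            periodic = c(TRUE, TRUE, TRUE))
  graph <- neighbor_list(o_config, cutoff = 1.2 * r_oo, method = "brute")
  deg <- tabulate(c(graph$pairs$i, graph$pairs$j), nbins = nrow(pos))
  if (any(deg != 4L)) {
    stop(sprintf(
      "cannot decorate protons: O-O contact graph is not 4-regular (degrees %d..%d); noise too large or lattice defective",
      min(deg), max(deg)
    ))
  }
  p <- graph$pairs
  ne <- nrow(p)
  n <- nrow(pos)

  orient <- NULL
  for (restart in seq_len(max_restarts)) {
    # TRUE: i donates to j; FALSE: j donates to i
    orient <- stats::runif(ne) < 0.5
    for (sweep in seq_len(max_sweeps)) {
      donors <- ifelse(orient, p$i, p$j)
      out_deg <- tabulate(donors, nbins = n)
      over <- which(out_deg > 2L)
      if (!length(over)) break
      # flip one random edge out of each over-donating oxygen, preferring
      # edges whose acceptor is under-donating
      for (v in sample(over)) {
        ev <- which(donors == v)
        if (!length(ev)) next
        acceptors <- ifelse(orient[ev], p$j[ev], p$i[ev])
        pick <- ev[acceptors %in% which(out_deg < 2L)]
        e <- if (length(pick)) pick[sample.int(length(pick), 1L)] else
          ev[sample.int(length(ev), 1L)]
        orient[e] <- !orient[e]
        donors <- ifelse(orient, p$i, p$j)
        out_deg <- tabulate(donors, nbins = n)
      }
    }
    donors <- ifelse(orient, p$i, p$j)
    if (all(tabulate(donors, nbins = n) == 2L)) break
    orient <- NULL
  }
  if (is.null(orient)) stop("ice-rule proton assignment did not converge")

  donors <- ifelse(orient, p$i, p$j)
  disp <- as.matrix(p[, c("dx", "dy", "dz")])
  disp[!orient, ] <- -disp[!orient, , drop = FALSE]  # donor -> acceptor
  h_pos <- pos[donors, , drop = FALSE] + r_oh * disp / p$r

  # assemble O, H1, H2 per molecule
  ord <- order(donors)
  h_by_o <- matrix(ord, ncol = 2L, byrow = TRUE)  # rows follow sorted donor ids
  coords <- matrix(NA_real_, 3L * n, 3L)
  names_out <- character(3L * n)
  mol <- integer(3L * n)
  for (k in seq_len(n)) {
    rows <- (3L * (k - 1L) + 1L):(3L * k)
    coords[rows[1L], ] <- pos[k, ]
    coords[rows[2L], ] <- h_pos[h_by_o[k, 1L], ]
    coords[rows[3L], ] <- h_pos[h_by_o[k, 2L], ]
    names_out[rows] <- c("OW", "HW1", "HW2")
    mol[rows] <- k
  }
  configuration(names_out, wrap_coords(coords, box), box, molecule_ids = mol,
                periodic = c(TRUE, TRUE, TRUE))
}
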