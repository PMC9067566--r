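#' Molecular configuration in an orthorhombic box
#'
#' The basic container used throughout the package: atom names, per-atom
#' molecule ids, Cartesian coordinates in angstrom, three orthorhombic box
#' edges and per-axis periodicity flags.  The slab convention is that `z` is
#' the non-periodic interface normal, so the default flags are
#' `c(TRUE, TRUE, FALSE)`.  Only orthorhombic cells are supported; triclinic
#' input is rejected at the I/O layer.
#'
#' @param atom_names Character vector of short atom names (e.g. `"OW"`).
#' @param coords Numeric n x 3 matrix of coordinates (angstrom).
#' @param box Length-3 numeric vector of box edges (Lx, Ly, Lz), angstrom.
#' @param molecule_ids Integer vector, one non-negative id per atom.
#'   Defaults to one molecule per atom.
#' @param periodic Length-3 logical periodicity flags.
#' @return An object of class `configuration`.
#' @export
configuration <- function(atom_names, coords, box,
                          molecule_ids = seq_along(atom_names),
                          periodic = c(TRUE, TRUE, FALSE)) {
  coords <- as.matrix(coords)
  if (length(atom_names) == 0L) {
    coords <- matrix(numeric(0), nrow = 0L, ncol = 3L)
  }
  if (ncol(coords) != 3L) stop("'coords' must have 3 columns")
  if (nrow(coords) != length(atom_names)) {
    stop("number of atom names must equal the number of coordinate rows")
  }
  if (length(molecule_ids) != length(atom_names)) {
    stop("'molecule_ids' must have one entry per atom")
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0)) {
    stop("'box' must be three positive finite edge lengths")
  }
  if (length(periodic) != 3L || !is.logical(periodic) || anyNA(periodic)) {
    stop("'periodic' must be three non-missing logicals")
  }
  molecule_ids <- as.integer(molecule_ids)
  if (anyNA(molecule_ids) || any(molecule_ids < 0L)) {
    stop("molecule ids must be non-negative integers")
  }
  structure(
    list(
      atom_names = as.character(atom_names),
      molecule_ids = molecule_ids,
      coords = unname(coords),
      box = as.numeric(box),
      periodic = periodic
    ),
    class = "configuration"
  )
}

#' Number of atoms in a configuration
#' @param config A `configuration`.
#' @return Integer atom count.
#' @export
n_atoms <- function(config) {
  stopifnot(inherits(config, "configuration"))
  length(config$atom_names)
}

#' Subset a configuration by atom indices
#'
#' @param config A `configuration`.
#' @param idx Integer atom indices (1-based) to keep, in the requested order.
#' @return A new `configuration` holding only those atoms.
#' @export
subset_configuration <- function(config, idx) {
  stopifnot(inherits(config, "configuration"))
  configuration(
    atom_names = config$atom_names[idx],
    coords = config$coords[idx, , drop = FALSE],
    box = config$box,
    molecule_ids = config$molecule_ids[idx],
    periodic = config$periodic
  )
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf(
    "<configuration> %d atoms, %d molecules, box %.2f x %.2f x %.2f A, pbc [%s]\n",
    n_atoms(x), length(unique(x$molecule_ids)),
    x$box[1], x$box[2], x$box[3],
    paste(ifelse(x$periodic, "T", "F"), collapse = " ")
  ))
  invisible(x)
}

#' Ordered sequence of configurations
#'
#' Frames must share atom count and atom ordering; times are in ps and must
#' be strictly increasing.
#'
#' @param frames List of `configuration` objects.
#' @param times Numeric vector of frame times (ps).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frames, times = seq_along(frames) - 1) {
  if (!length(frames)) stop("a trajectory needs at least one frame")
  if (!all(vapply(frames, inherits, logical(1), "configuration"))) {
    stop("all frames must be configurations")
  }
  if (length(times) != length(frames)) stop("one time per frame required")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  n0 <- n_atoms(frames[[1L]])
  nm0 <- frames[[1L]]$atom_names
  for (f in frames) {
    if (n_atoms(f) != n0 || !identical(f$atom_names, nm0)) {
      stop("all frames must have identical atom count and ordering")
    }
  }
  structure(list(frames = frames, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %g .. %g ps\n",
              length(x$frames), n_atoms(x$frames[[1L]]),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}
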