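# Structure file dialects.
#
# extended XYZ: atom count, then a comment line carrying Lattice="ax ... cz"
# (9 numbers, row-major cell matrix; off-diagonal entries must be zero),
# Properties=species:S:1:pos:R:3[:mol:I:1] and pbc="T T F".  Coordinates in
# angstrom.  Plain XYZ without a Lattice key is rejected: a configuration is
# meaningless here without its box.
#
# GRO fixed format: coordinates in nm (multiplied by 10 on read), 1-based
# residue/atom numbering, %8.3f coordinate fields, free-format box line in
# nm.  A box line with non-zero triclinic components is rejected.

parse_error <- function(path, line, msg) {
  stop(sprintf("parse error at line %d of '%s': %s", line, path, msg),
       call. = FALSE)
}

extract_key <- function(comment, key) {
  m <- regmatches(comment, regexec(paste0(key, '="([^"]*)"'), comment))[[1L]]
  if (length(m) < 2L) return(NULL)
  m[2L]
}

parse_lattice <- function(comment, path, line) {
  lat <- extract_key(comment, "Lattice")
  if (is.null(lat)) {
    parse_error(path, line, 'missing Lattice="..." key (plain XYZ without a box is not accepted)')
  }
  v <- suppressWarnings(as.numeric(strsplit(trimws(lat), "\\s+")[[1L]]))
  if (length(v) != 9L || anyNA(v)) {
    parse_error(path, line, "Lattice key must hold 9 numbers")
  }
  off <- v[c(2, 3, 4, 6, 7, 8)]
  if (any(abs(off) > 1e-9)) {
    parse_error(path, line, "triclinic cells are not supported (off-diagonal lattice entries must be zero)")
  }
  v[c(1, 5, 9)]
}

parse_pbc <- function(comment) {
  p <- extract_key(comment, "pbc")
  if (is.null(p)) return(c(TRUE, TRUE, FALSE))
  toks <- strsplit(trimws(p), "\\s+")[[1L]]
  if (length(toks) != 3L) return(c(TRUE, TRUE, FALSE))
  toupper(substr(toks, 1, 1)) == "T"
}

read_xyz_frame <- function(lines, start, path) {
  nat <- suppressWarnings(as.integer(trimws(lines[start])))
  if (is.na(nat) || nat < 0L) parse_error(path, start, "expected an atom count")
  if (start + 1L + nat > length(lines) + 0L && nat > 0L) {
    parse_error(path, length(lines), "truncated frame: fewer atom lines than the stated count")
  }
  comment <- if (length(lines) >= start + 1L) lines[start + 1L] else ""
  box <- parse_lattice(comment, path, start + 1L)
  if (any(box <= 0)) parse_error(path, start + 1L, "box edges must be positive")
  periodic <- parse_pbc(comment)
  tm <- extract_key(comment, "Time")
  time <- if (is.null(tm)) NA_real_ else suppressWarnings(as.numeric(tm))
  props <- regmatches(comment, regexec("Properties=([^ ]+)", comment))[[1L]]
  has_mol <- length(props) >= 2L && grepl("mol:I:1", props[2L], fixed = TRUE)

  nm <- character(nat); mol <- integer(nat)
  xyz <- matrix(NA_real_, nat, 3L)
  for (k in seq_len(nat)) {
    ln <- start + 1L + k
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    need <- if (has_mol) 5L else 4L
    if (length(toks) < need) parse_error(path, ln, "too few fields on atom line")
    vals <- suppressWarnings(as.numeric(toks[2:4]))
    if (anyNA(vals)) parse_error(path, ln, "non-numeric coordinate")
    nm[k] <- toks[1L]
    xyz[k, ] <- vals
    mol[k] <- if (has_mol) {
      mv <- suppressWarnings(as.integer(toks[5L]))
      if (is.na(mv)) parse_error(path, ln, "non-integer molecule id")
      mv
    } else k
  }
  list(
    config = configuration(nm, xyz, box, molecule_ids = mol, periodic = periodic),
    time = time,
    next_line = start + 2L + nat
  )
}

read_gro_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) parse_error(path, length(lines), "GRO file too short")
  nat <- suppressWarnings(as.integer(trimws(lines[2L])))
  if (is.na(nat) || nat < 0L) parse_error(path, 2L, "expected an atom count")
  if (length(lines) < 3L + nat) {
    parse_error(path, length(lines), "truncated GRO file: missing atom or box lines")
  }
  nm <- character(nat); mol <- integer(nat)
  xyz <- matrix(NA_real_, nat, 3L)
  for (k in seq_len(nat)) {
    ln <- 2L + k
    s <- lines[ln]
    if (nchar(s) < 44L) parse_error(path, ln, "GRO atom line shorter than 44 characters")
    mol[k] <- suppressWarnings(as.integer(substr(s, 1L, 5L)))
    nm[k] <- trimws(substr(s, 11L, 15L))
    vals <- suppressWarnings(as.numeric(c(
      substr(s, 21L, 28L), substr(s, 29L, 36L), substr(s, 37L, 44L)
    )))
    if (is.na(mol[k])) parse_error(path, ln, "non-integer residue number")
    if (anyNA(vals)) parse_error(path, ln, "non-numeric coordinate")
    xyz[k, ] <- vals * 10  # nm -> angstrom
  }
  bline <- 3L + nat
  bv <- suppressWarnings(as.numeric(strsplit(trimws(lines[bline]), "\\s+")[[1L]]))
  if (length(bv) < 3L || anyNA(bv[1:3])) {
    parse_error(path, bline, "missing or malformed box line")
  }
  if (length(bv) > 3L && any(abs(bv[-(1:3)]) > 1e-9)) {
    parse_error(path, bline, "triclinic GRO boxes are not supported")
  }
  box <- bv[1:3] * 10
  if (any(box <= 0)) parse_error(path, bline, "box edges must be positive")
  configuration(nm, xyz, box, molecule_ids = mol,
                periodic = c(TRUE, TRUE, FALSE))
}

#' Read a molecular configuration
#'
#' @param path File path.
#' @param format `"xyz_ext"` (extended XYZ with Lattice header) or `"gro"`.
#'   GRO coordinates are converted from nm to angstrom on read.
#' @return A [configuration].
#' @export
read_configuration <- function(path, format = c("xyz_ext", "gro")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  if (format == "gro") return(read_gro_file(path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) parse_error(path, 1L, "empty file")
  read_xyz_frame(lines, 1L, path)$config
}

gro_resname <- function(atom_names) {
  if (any(atom_names %in% c("OW", "HW1", "HW2"))) "SOL"
  else if (any(atom_names %in% c("C3", "C25"))) "CHL"
  else "MOL"
}

format_xyz_frame <- function(config, time = NULL) {
  box <- config$box
  lattice <- sprintf("%.10g %.10g %.10g", box[1], box[2], box[3])
  comment <- sprintf(
    'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=species:S:1:pos:R:3:mol:I:1 pbc="%s"',
    box[1], box[2], box[3],
    paste(ifelse(config$periodic, "T", "F"), collapse = " ")
  )
  if (!is.null(time) && is.finite(time)) {
    comment <- sprintf('%s Time="%.10g"', comment, time)
  }
  atoms <- sprintf("%-5s %17.10f %17.10f %17.10f %8d",
                   config$atom_names,
                   config$coords[, 1], config$coords[, 2], config$coords[, 3],
                   config$molecule_ids)
  c(sprintf("%d", n_atoms(config)), comment, atoms)
}

format_gro <- function(config, title = "written by slabice") {
  by_mol <- split(seq_len(n_atoms(config)), config$molecule_ids)
  lines <- character(n_atoms(config))
  for (mol_chr in names(by_mol)) {
    idx <- by_mol[[mol_chr]]
    res <- gro_resname(config$atom_names[idx])
    for (i in idx) {
      lines[i] <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                          as.integer(mol_chr) %% 100000L, res,
                          substr(config$atom_names[i], 1L, 5L),
                          i %% 100000L,
                          config$coords[i, 1] / 10,
                          config$coords[i, 2] / 10,
                          config$coords[i, 3] / 10)
    }
  }
  c(title, sprintf("%5d", n_atoms(config)), lines,
    sprintf("%10.5f%10.5f%10.5f",
            config$box[1] / 10, config$box[2] / 10, config$box[3] / 10))
}

#' Write a molecular configuration
#'
#' The written file round-trips through [read_configuration()] up to format
#' precision (GRO stores nm to three decimals, i.e. 0.01 angstrom).
#' Writing an empty configuration is refused.
#'
#' @param config A [configuration].
#' @param path Output path.
#' @param format `"xyz_ext"` or `"gro"`.
#' @return Invisibly, `path`.
#' @export
write_configuration <- function(config, path, format = c("xyz_ext", "gro")) {
  stopifnot(inherits(config, "configuration"))
  format <- match.arg(format)
  if (n_atoms(config) == 0L) {
    stop("refusing to write a configuration with no atoms")
  }
  lines <- if (format == "gro") format_gro(config) else format_xyz_frame(config)
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                            conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Read a multi-frame extended-XYZ trajectory
#'
#' @param path File of concatenated extended-XYZ frames; each comment line
#'   may carry a `Time="..."` key (ps).
#' @return A [trajectory].
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  frames <- list(); times <- numeric(0)
  at <- 1L
  while (at <= length(lines) && nzchar(trimws(lines[at]))) {
    fr <- read_xyz_frame(lines, at, path)
    frames[[length(frames) + 1L]] <- fr$config
    times <- c(times, fr$time)
    at <- fr$next_line
  }
  if (anyNA(times)) times <- seq_along(frames) - 1
  trajectory(frames, times)
}

#' Write a trajectory as concatenated extended XYZ
#'
#' @param traj A [trajectory].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  out <- unlist(lapply(seq_along(traj$frames), function(i) {
    format_xyz_frame(traj$frames[[i]], time = traj$times[i])
  }))
  writeLines(out, path)
  invisible(path)
}
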