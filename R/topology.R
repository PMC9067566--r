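#' Classify atoms into molecular roles
#'
#' Groups atoms by molecule id and assigns each molecule a role under the
#' declared naming scheme.  The default scheme recognises three-site waters
#' (`OW`, `HW1`, `HW2`) and the two-site cholesterol surrogate used by the
#' monolayer generator: a rigid rod whose axis runs from the tail carbon
#' `C25` to the head carbon `C3`, with a hydroxyl head group (`O1`, `H1`).
#' Waters are validated to carry exactly one oxygen and two hydrogens.
#'
#' @param config A [configuration].
#' @param naming_scheme Currently only `"default"`.
#' @param strict If `TRUE` (default), an unrecognised molecule is an error;
#'   otherwise it is filed under `other`.
#' @return An object of class `molecule_topology` with components
#'   `water` (data frame: `mol`, `O`, `H1`, `H2` atom indices),
#'   `chol` (data frame: `mol`, `axis_tail`, `axis_head`, `oh_O`, `oh_H`)
#'   and `other` (integer atom indices).
#' @export
infer_topology <- function(config, naming_scheme = "default", strict = TRUE) {
  stopifnot(inherits(config, "configuration"))
  naming_scheme <- match.arg(naming_scheme)
  by_mol <- split(seq_len(n_atoms(config)), config$molecule_ids)

  water <- list()
  chol <- list()
  other <- integer(0)

  for (mol_chr in names(by_mol)) {
    idx <- by_mol[[mol_chr]]
    nms <- config$atom_names[idx]
    mol <- as.integer(mol_chr)
    if (any(nms %in% c("OW", "HW1", "HW2"))) {
      o <- idx[nms == "OW"]
      h <- idx[grepl("^HW", nms)]
      if (length(o) != 1L || length(h) != 2L || length(idx) != 3L) {
        stop(sprintf(
          "molecule %d looks like water but has %d O and %d H atoms (want 1 O + 2 H)",
          mol, length(o), length(h)
        ))
      }
      water[[length(water) + 1L]] <- c(mol = mol, O = o, H1 = h[1L], H2 = h[2L])
    } else if (all(c("C3", "C25") %in% nms)) {
      tail_i <- idx[nms == "C25"]
      head_i <- idx[nms == "C3"]
      oh_o <- idx[nms == "O1"]
      oh_h <- idx[nms == "H1"]
      if (length(oh_o) != 1L || length(oh_h) != 1L) {
        stop(sprintf("surrogate cholesterol molecule %d lacks its hydroxyl (O1, H1)", mol))
      }
      if (identical(tail_i, head_i)) {
        stop(sprintf("molecule %d: axis tail and head must be distinct atoms", mol))
      }
      chol[[length(chol) + 1L]] <- c(
        mol = mol, axis_tail = tail_i, axis_head = head_i,
        oh_O = oh_o, oh_H = oh_h
      )
    } else if (strict) {
      stop(sprintf(
        "molecule %d has unrecognised atom names under scheme '%s': %s",
        mol, naming_scheme, paste(unique(nms), collapse = ", ")
      ))
    } else {
      other <- c(other, idx)
    }
  }

  as_df <- function(rows, cols) {
    if (!length(rows)) {
      out <- as.data.frame(matrix(integer(0), ncol = length(cols)))
      names(out) <- cols
      return(out)
    }
    as.data.frame(do.call(rbind, rows))
  }

  structure(
    list(
      water = as_df(water, c("mol", "O", "H1", "H2")),
      chol = as_df(chol, c("mol", "axis_tail", "axis_head", "oh_O", "oh_H")),
      other = other,
      n_atoms = n_atoms(config),
      naming_scheme = naming_scheme
    ),
    class = "molecule_topology"
  )
}

#' @export
print.molecule_topology <- function(x, ...) {
  cat(sprintf("<molecule_topology> %d waters, %d surrogate cholesterols, %d other atoms\n",
              nrow(x$water), nrow(x$chol), length(x$other)))
  invisible(x)
}

#' Extract the water-oxygen sub-configuration
#'
#' Order-parameter and nucleation analyses represent each water molecule by
#' its oxygen.  Returns the oxygen-only configuration together with the
#' molecule id of each retained atom.
#'
#' @param config A [configuration].
#' @param topology Matching [infer_topology()] result; computed when `NULL`.
#' @return List with `config` (oxygens only) and `mol` (molecule ids).
#' @export
water_oxygen_config <- function(config, topology = NULL) {
  if (is.null(topology)) topology <- infer_topology(config)
  o <- topology$water$O
  list(config = subset_configuration(config, o), mol = topology$water$mol)
}
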