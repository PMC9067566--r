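#' Build a neighbour graph under minimum image
#'
#' Collects all atom pairs whose minimum-image distance is less than or
#' equal to `cutoff` (the cutoff is inclusive: ties at the cutoff are kept).
#' `"brute"` compares all pairs; `"cell"` uses a linked-cell grid and
#' returns an identical graph, but requires the periodic box edges to
#' accommodate at least three cells of size `cutoff`.
#'
#' @param config A [configuration].
#' @param cutoff Neighbour cutoff (angstrom); must be positive and, for the
#'   cell method, at most half the smallest periodic box edge.
#' @param method `"cell"` or `"brute"`.
#' @return An object of class `neighbor_graph`: `pairs` (data frame `i`,
#'   `j`, `dx`, `dy`, `dz`, `r` with `i < j`; displacement points from `i`
#'   to `j`), `adj` (per-atom neighbour index lists), plus the cutoff and
#'   periodicity flags used.
#' @export
neighbor_list <- function(config, cutoff, method = c("cell", "brute")) {
  stopifnot(inherits(config, "configuration"))
  method <- match.arg(method)
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be positive")
  n <- n_atoms(config)
  x <- config$coords
  box <- config$box
  per <- config$periodic

  pairs <- if (n < 2L) {
    matrix(numeric(0), 0L, 6L)
  } else if (method == "brute") {
    neighbor_pairs_brute(x, box, per, cutoff)
  } else {
    p_edges <- box[per]
    if (length(p_edges) && cutoff > min(p_edges) / 2) {
      stop("cutoff exceeds half the smallest periodic box edge; use method = 'brute'")
    }
    if (length(p_edges) && any(floor(p_edges / cutoff) < 3)) {
      stop("box too small for the cell method at this cutoff; use method = 'brute'")
    }
    neighbor_pairs_cell(x, box, per, cutoff)
  }

  colnames(pairs) <- c("i", "j", "dx", "dy", "dz", "r")
  adj <- vector("list", n)
  if (nrow(pairs)) {
    tmp <- split(c(pairs[, "j"], pairs[, "i"]),
                 factor(c(pairs[, "i"], pairs[, "j"]), levels = seq_len(n)))
    adj <- lapply(tmp, as.integer)
  } else {
    adj <- replicate(n, integer(0), simplify = FALSE)
  }

  structure(
    list(pairs = as.data.frame(pairs), adj = adj, n_atoms = n,
         cutoff = cutoff, periodic = per, method = method),
    class = "neighbor_graph"
  )
}

# all-pairs search, vectorised over the second index
neighbor_pairs_brute <- function(x, box, per, cutoff) {
  n <- nrow(x)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    d <- x[j, , drop = FALSE] -
      matrix(x[i, ], nrow = length(j), ncol = 3L, byrow = TRUE)
    d <- minimum_image(d, box, per)
    r2 <- rowSums(d * d)
    keep <- which(r2 <= cutoff^2)
    if (length(keep)) {
      out[[i]] <- cbind(i, j[keep], d[keep, , drop = FALSE], sqrt(r2[keep]))
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) matrix(numeric(0), 0L, 6L) else do.call(rbind, out)
}

neighbor_pairs_cell <- function(x, box, per, cutoff) {
  n <- nrow(x)
  # cell counts; non-periodic axes use the coordinate range
  lo <- numeric(3); n_cell <- integer(3)
  for (k in 1:3) {
    if (per[k]) {
      lo[k] <- 0
      n_cell[k] <- max(1L, floor(box[k] / cutoff))
    } else {
      rng <- range(x[, k])
      lo[k] <- rng[1]
      n_cell[k] <- max(1L, floor((rng[2] - rng[1]) / cutoff) + 1L)
    }
  }
  ci <- matrix(0L, n, 3L)
  for (k in 1:3) {
    f <- floor((x[, k] - lo[k]) / (if (per[k]) box[k] / n_cell[k] else cutoff))
    if (per[k]) f <- ((f %% n_cell[k]) + n_cell[k]) %% n_cell[k]
    else f <- pmin(pmax(f, 0), n_cell[k] - 1L)
    ci[, k] <- as.integer(f)
  }
  key <- ci[, 1] + n_cell[1] * (ci[, 2] + n_cell[2] * ci[, 3])
  members <- split(seq_len(n), key)
  occ <- as.integer(names(members))
  occ_pos <- cbind(occ %% n_cell[1],
                   (occ %/% n_cell[1]) %% n_cell[2],
                   occ %/% (n_cell[1] * n_cell[2]))
  lookup <- new.env(hash = TRUE, size = length(members))
  for (m in seq_along(members)) assign(as.character(occ[m]), members[[m]], lookup)

  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  out <- list()
  for (m in seq_along(members)) {
    a <- members[[m]]
    base <- occ_pos[m, ]
    for (o in seq_len(nrow(offsets))) {
      nb <- base + offsets[o, ]
      ok <- TRUE
      for (k in 1:3) {
        if (per[k]) nb[k] <- ((nb[k] %% n_cell[k]) + n_cell[k]) %% n_cell[k]
        else if (nb[k] < 0 || nb[k] >= n_cell[k]) { ok <- FALSE; break }
      }
      if (!ok) next
      nb_key <- nb[1] + n_cell[1] * (nb[2] + n_cell[2] * nb[3])
      b <- lookup[[as.character(nb_key)]]
      if (is.null(b)) next
      # evaluate each (a_i, b_j) pair once, keeping i < j
      ii <- rep(a, each = length(b))
      jj <- rep(b, times = length(a))
      keep <- ii < jj
      if (!any(keep)) next
      ii <- ii[keep]; jj <- jj[keep]
      d <- x[jj, , drop = FALSE] - x[ii, , drop = FALSE]
      d <- minimum_image(d, box, per)
      r2 <- rowSums(d * d)
      sel <- which(r2 <= cutoff^2)
      if (length(sel)) {
        out[[length(out) + 1L]] <-
          cbind(ii[sel], jj[sel], d[sel, , drop = FALSE], sqrt(r2[sel]))
      }
    }
  }
  if (!length(out)) return(matrix(numeric(0), 0L, 6L))
  res <- do.call(rbind, out)
  res[!duplicated(res[, 1:2, drop = FALSE]), , drop = FALSE]
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat(sprintf("<neighbor_graph> %d atoms, %d pairs, cutoff %.3g A (%s)\n",
              x$n_atoms, nrow(x$pairs), x$cutoff, x$method))
  invisible(x)
}

graph_fingerprint <- function(graph) {
  c(n = graph$n_atoms, e = nrow(graph$pairs), cut = graph$cutoff)
}
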