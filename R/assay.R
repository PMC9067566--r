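# Droplet-freezing assay statistics under the singular (site-specific)
# model.
#
# Fraction frozen f(T): share of droplets frozen at or above T (censored
# droplets stay in the denominator).  Cumulative nucleation sites per
# substrate molecule: n_mol(T) = -ln(1 - f(T)) / molecules_per_droplet.
# Confidence bands: the observed event count in each temperature interval
# is taken as the Poisson mean, many replicate event tables are drawn, and
# the band is the (10th, 90th) percentile range of the replicate n_mol
# values at each grid point.

assay_grid <- function(assay, bin_width = NULL) {
  bw <- bin_width %||% assay$meta$bin_width
  seq(assay$meta$T_start, assay$meta$T_end, by = -bw)
}

#' Fraction of droplets frozen
#'
#' @param assay A `freezing_assay`.
#' @param grid Descending temperature grid (deg C); defaults to the
#'   assay's own measurement grid.
#' @return Numeric f(T) on the grid, non-decreasing on cooling.
#' @export
fraction_frozen <- function(assay, grid = NULL) {
  stopifnot(inherits(assay, "freezing_assay"))
  if (!nrow(assay$droplets)) stop("assay contains no droplets")
  if (is.null(grid)) grid <- assay_grid(assay)
  if (any(grid > assay$meta$T_start + 1e-9) ||
      any(grid < assay$meta$T_end - 1e-9)) {
    stop("grid extends beyond the assay's temperature range")
  }
  tf <- assay$droplets$T_freeze
  tf <- tf[!assay$droplets$censored & !is.na(tf)]
  n <- nrow(assay$droplets)
  vapply(grid, function(T) sum(tf >= T - 1e-9) / n, numeric(1))
}

#' Cumulative nucleation sites per molecule
#'
#' `n_mol(T) = -ln(1 - f(T)) / molecules_per_droplet`.  Grid points with
#' `f = 1` are undefined under the singular model; they are returned as
#' `NA` (never infinite) and flagged in the `truncated` attribute.
#'
#' @param f Fraction frozen on a grid (values in \[0, 1\]).
#' @param molecules_per_droplet Substrate molecules per droplet (> 0).
#' @return n_mol on the same grid, with attribute `truncated` (indices
#'   where `f = 1`).
#' @export
nmol <- function(f, molecules_per_droplet) {
  if (molecules_per_droplet <= 0) stop("'molecules_per_droplet' must be positive")
  if (any(f < -1e-12 | f > 1 + 1e-12)) stop("'f' must lie in [0, 1]")
  sat <- which(f >= 1)
  out <- -log1p(-pmin(f, 1)) / molecules_per_droplet
  out[sat] <- NA_real_
  attr(out, "truncated") <- sat
  out
}

# events per left-closed temperature bin, binned by freezing temperature
bin_events <- function(assay, grid) {
  tf <- assay$droplets$T_freeze
  tf <- tf[!assay$droplets$censored & !is.na(tf)]
  k <- integer(length(grid))
  if (!length(tf)) return(k)
  bw <- if (length(grid) > 1L) grid[1L] - grid[2L] else assay$meta$bin_width
  idx <- floor((grid[1L] - tf) / bw + 1e-9) + 1L
  idx <- pmin(pmax(idx, 1L), length(grid))
  tab <- tabulate(idx, nbins = length(grid))
  as.integer(tab)
}

#' Poisson Monte-Carlo confidence band for n_mol
#'
#' For each temperature interval the observed number of freezing events is
#' taken as the Poisson expectation; `n_draws` replicate event tables are
#' drawn, accumulated into replicate n_mol curves, and the band is the
#' requested percentile range at each grid point.  Replicates whose
#' cumulative count saturates the droplet population give an undefined
#' n_mol there; if a percentile lands on such replicates the band is `NA`
#' at that grid point and flagged.
#'
#' @param assay A `freezing_assay`.
#' @param bin_width Interval width (K); defaults to the assay's.
#' @param n_draws Number of Poisson replicates (>= 2).
#' @param percentiles Lower/upper percentile pair (default 10 and 90).
#' @param seed RNG seed (recorded in the result).
#' @return List with `grid`, `lower`, `upper`, `k` (observed events per
#'   bin), `n_draws`, `percentiles`, `seed`.
#' @export
poisson_mc_ci <- function(assay, bin_width = NULL, n_draws = 1000L,
                          percentiles = c(10, 90), seed = 1L) {
  stopifnot(inherits(assay, "freezing_assay"))
  if (n_draws < 2L) stop("'n_draws' must be >= 2")
  if (length(percentiles) != 2L || any(percentiles < 0 | percentiles > 100)) {
    stop("'percentiles' must be two values in [0, 100]")
  }
  grid <- assay_grid(assay, bin_width)
  k <- bin_events(assay, grid)
  n <- assay$meta$n_droplets
  X <- assay$meta$molecules_per_droplet
  nb <- length(grid)
  band <- with_seed(seed, {
    draws <- matrix(stats::rpois(n_draws * nb, rep(k, each = n_draws)),
                    n_draws, nb)
    cum <- t(apply(draws, 1L, cumsum))
    cum <- pmin(cum, n)
    f_rep <- cum / n
    n_rep <- -log1p(-f_rep) / X  # Inf where f = 1
    apply(n_rep, 2L, stats::quantile, probs = percentiles / 100,
          names = FALSE, type = 7)
  })
  lower <- band[1L, ]; upper <- band[2L, ]
  truncated <- which(!is.finite(upper) | !is.finite(lower))
  lower[!is.finite(lower)] <- NA_real_
  upper[!is.finite(upper)] <- NA_real_
  list(grid = grid, lower = lower, upper = upper, k = k,
       truncated = truncated, n_draws = as.integer(n_draws),
       percentiles = percentiles, seed = seed)
}

#' Assemble the full n_mol curve of an assay
#'
#' Convenience wrapper: fraction frozen, n_mol and the Monte-Carlo band on
#' a common grid.
#'
#' @inheritParams poisson_mc_ci
#' @return An object of class `nmol_curve`: `grid` (descending deg C),
#'   `f`, `n_mol`, `ci_lower`, `ci_upper`, `truncated`, and `meta`.
#' @export
nmol_curve <- function(assay, bin_width = NULL, n_draws = 1000L,
                       percentiles = c(10, 90), seed = 1L) {
  grid <- assay_grid(assay, bin_width)
  f <- fraction_frozen(assay, grid)
  nm <- nmol(f, assay$meta$molecules_per_droplet)
  ci <- poisson_mc_ci(assay, bin_width = bin_width, n_draws = n_draws,
                      percentiles = percentiles, seed = seed)
  structure(
    list(grid = grid, f = f, n_mol = as.numeric(nm),
         ci_lower = ci$lower, ci_upper = ci$upper,
         truncated = union(attr(nm, "truncated"), ci$truncated),
         meta = list(bin_width = bin_width %||% assay$meta$bin_width,
                     n_draws = ci$n_draws, percentiles = percentiles,
                     seed = seed,
                     molecules_per_droplet = assay$meta$molecules_per_droplet,
                     n_droplets = assay$meta$n_droplets)),
    class = "nmol_curve"
  )
}

#' @export
print.nmol_curve <- function(x, ...) {
  cat(sprintf("<nmol_curve> %d grid points (%g .. %g C), f up to %.3f\n",
              length(x$grid), x$grid[1], x$grid[length(x$grid)], max(x$f)))
  invisible(x)
}

#' Subtract a background site spectrum
#'
#' Works on the differential (per-bin) site spectra: the per-bin increments
#' of the two cumulative curves are subtracted, floored at zero, and
#' re-accumulated.  Bins where the background increment is at least the
#' sample increment are flagged.  Both curves must share a grid and a
#' normalisation (convert a per-droplet background to per-molecule with the
#' sample's molecules-per-droplet before calling).  The Monte-Carlo band is
#' not propagated through the subtraction and is returned as `NA`.
#'
#' @param sample_curve,background_curve `nmol_curve` objects on a common
#'   grid.
#' @return An `nmol_curve` for the background-subtracted signal, with
#'   `flagged_bins` marking bins dominated by background.
#' @export
subtract_background <- function(sample_curve, background_curve) {
  stopifnot(inherits(sample_curve, "nmol_curve"),
            inherits(background_curve, "nmol_curve"))
  if (length(sample_curve$grid) != length(background_curve$grid) ||
      any(abs(sample_curve$grid - background_curve$grid) > 1e-9)) {
    stop("sample and background curves are on different grids")
  }
  ds <- diff(c(0, sample_curve$n_mol))
  db <- diff(c(0, background_curve$n_mol))
  flagged <- which(is.na(ds) | is.na(db) | db >= ds)
  d <- pmax(ds - db, 0)
  out <- sample_curve
  out$n_mol <- cumsum(d)
  out$f <- NA_real_
  out$ci_lower <- rep(NA_real_, length(out$grid))
  out$ci_upper <- rep(NA_real_, length(out$grid))
  out$flagged_bins <- flagged
  out$meta$background_subtracted <- TRUE
  out
}
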