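# Surface tension and surface pressure from pressure-tensor traces.
#
# For a slab with two equivalent interfaces normal to z:
#   gamma = (L_z / 2) ( <P_zz> - (<P_xx> + <P_yy>) / 2 ),  1 bar A = 0.01 mN/m
#   pi    = gamma_water_vacuum - 2 gamma
# The factor two accounts for the two coated interfaces in the slab setup;
# gamma_water_vacuum defaults to 80.1 mN/m (TIP4P/Ice at ambient
# conditions).

#' Surface tension from a pressure-tensor trace
#'
#' Point estimate from the full trace; the standard error comes from block
#' averaging (contiguous blocks, block-mean standard deviation over
#' sqrt(blocks)).  The returned object also carries the surface pressure
#' `pi = gamma_water_vacuum - 2 gamma`, so the identity holds by
#' construction for every emitted result.
#'
#' @param trace A [generate_pressure_trace()] result, or any object of
#'   class `pressure_trace` (list with `data` columns `P_xx`, `P_yy`,
#'   `P_zz` and scalar `L_z` in angstrom).
#' @param block_count Number of blocks for the error estimate (>= 2).
#' @param gamma_water_vacuum Clean-interface surface tension (mN/m).
#' @return An object of class `surface_tension_result`: `gamma`, `se`
#'   (mN/m), `pi`, `pi_se`, `gamma_water_vacuum`, `block_count`, `n`.
#' @export
surface_tension <- function(trace, block_count = 5L,
                            gamma_water_vacuum = 80.1) {
  stopifnot(inherits(trace, "pressure_trace"))
  d <- trace$data
  n <- nrow(d)
  if (block_count < 2L) stop("'block_count' must be >= 2")
  if (n < block_count) {
    stop(sprintf("trace has %d samples but %d blocks were requested", n,
                 block_count))
  }
  g_t <- .BAR_ANGSTROM_TO_MN_PER_M * (trace$L_z / 2) *
    (d$P_zz - (d$P_xx + d$P_yy) / 2)
  gamma <- mean(g_t)
  blocks <- split(g_t, cut(seq_len(n), block_count, labels = FALSE))
  bm <- vapply(blocks, mean, numeric(1))
  se <- stats::sd(bm) / sqrt(block_count)
  structure(
    list(gamma = gamma, se = se,
         pi = surface_pressure(gamma, gamma_water_vacuum),
         pi_se = 2 * se,
         gamma_water_vacuum = gamma_water_vacuum,
         block_count = as.integer(block_count), n = n, L_z = trace$L_z),
    class = "surface_tension_result"
  )
}

#' @export
print.surface_tension_result <- function(x, ...) {
  cat(sprintf("gamma = %.2f +/- %.2f mN/m; pi = %.2f +/- %.2f mN/m (gamma_wv = %.1f)\n",
              x$gamma, x$se, x$pi, x$pi_se, x$gamma_water_vacuum))
  invisible(x)
}

#' Surface pressure of a coated interface
#'
#' `pi = gamma_water_vacuum - 2 * gamma`, where `gamma` is the surface
#' tension of one coated water-vacuum interface and the factor two counts
#' the two coated interfaces of the slab setup.
#'
#' @param gamma Surface tension of the coated interface (mN/m).
#' @param gamma_water_vacuum Clean water-vacuum surface tension (mN/m).
#' @return Surface pressure (mN/m).
#' @export
surface_pressure <- function(gamma, gamma_water_vacuum = 80.1) {
  gamma_water_vacuum - 2 * gamma
}

#' Surface area per monolayer molecule
#'
#' @param x A [configuration] or a length-2/3 numeric box (angstrom).
#' @param n_per_leaflet Molecules in one leaflet (>= 1).
#' @return S_A/mol in angstrom^2.
#' @export
area_per_molecule <- function(x, n_per_leaflet) {
  if (inherits(x, "configuration")) x <- x$box
  if (n_per_leaflet < 1) stop("'n_per_leaflet' must be >= 1")
  x[1] * x[2] / n_per_leaflet
}

#' Isotherm point
#'
#' A (surface area per molecule, surface pressure) pair with uncertainty.
#'
#' @param S_A_per_mol Surface area per molecule (angstrom^2).
#' @param pi Surface pressure (mN/m).
#' @param pi_se Its standard error.
#' @return An object of class `isotherm_point`.
#' @export
isotherm_point <- function(S_A_per_mol, pi, pi_se = NA_real_) {
  if (S_A_per_mol <= 0) stop("'S_A_per_mol' must be positive")
  structure(list(S_A_per_mol = S_A_per_mol, pi = pi, pi_se = pi_se),
            class = "isotherm_point")
}
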