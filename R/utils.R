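# Internal unit conventions: length in angstrom, time in ps, temperature in K
# (assay temperatures in degrees C, stated where used), pressure in bar,
# surface tension in mN/m.  Conversions happen only at I/O boundaries.

# 1 bar * angstrom = 0.01 mN/m
.BAR_ANGSTROM_TO_MN_PER_M <- 0.01

#' Evaluate code under a fixed random seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so generators are pure functions of their seed
#' without clobbering the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Minimum-image displacement under per-axis periodicity
#'
#' Applies the minimum-image convention to a displacement (or a matrix of
#' displacements) only along the axes flagged periodic.  With all flags
#' `FALSE` the input is returned unchanged.
#'
#' @param d Numeric length-3 vector or an n x 3 matrix of displacements
#'   (angstrom).
#' @param box Length-3 box edges (angstrom).
#' @param periodic Length-3 logical periodicity flags; slab default
#'   `c(TRUE, TRUE, FALSE)`.
#' @return Displacement(s) of the same shape as `d`.
#' @export
minimum_image <- function(d, box, periodic = c(TRUE, TRUE, FALSE)) {
  vec <- is.null(dim(d))
  m <- if (vec) matrix(d, ncol = 3L) else d
  for (k in 1:3) {
    if (periodic[k]) m[, k] <- m[, k] - box[k] * round(m[, k] / box[k])
  }
  if (vec) as.numeric(m) else m
}

# wrap coordinate rows into [0, box) per axis
wrap_coords <- function(m, box) {
  for (k in 1:3) m[, k] <- m[, k] %% box[k]
  m
}

# Uniform random rotation matrix (Shoemake quaternion method).
random_rotation <- function() {
  u <- stats::runif(3)
  q <- c(
    sqrt(1 - u[1]) * sin(2 * pi * u[2]),
    sqrt(1 - u[1]) * cos(2 * pi * u[2]),
    sqrt(u[1]) * sin(2 * pi * u[3]),
    sqrt(u[1]) * cos(2 * pi * u[3])
  )
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# FNV-1a hash of a character scalar, as 8 hex digits; used to stamp run
# outputs with a config fingerprint without external dependencies.
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    # XOR into the low byte only (h may exceed the 32-bit signed range)
    h <- (h %/% 256) * 256 + bitwXor(h %% 256, b %% 256)
    # 32-bit modular multiply by the FNV prime 16777619, done in two halves
    # to stay inside double precision
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
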