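# Pressure-tensor traces and simulated cold-stage droplet freezing assays.

#' Generate a synthetic pressure-tensor trace
#'
#' Independent Gaussian samples per diagonal component, with the analytic
#' surface tension implied by the means attached as ground truth:
#' gamma = (L_z / 2) (P_zz - (P_xx + P_yy) / 2), converted at
#' 1 bar * angstrom = 0.01 mN/m.
#'
#' @param mean_P Length-3 means of (P_xx, P_yy, P_zz), bar.
#' @param sigma Per-component standard deviation, bar.
#' @param n_samples Number of samples (>= 2).
#' @param L_z Box height entering the surface-tension integral (angstrom).
#' @param seed RNG seed.
#' @param dt Sample spacing (ps).
#' @return An object of class `pressure_trace` (data frame `time`, `P_xx`,
#'   `P_yy`, `P_zz` plus `L_z`), with attribute `gamma_true` (mN/m).
#' @export
generate_pressure_trace <- function(mean_P = c(0, 0, 0), sigma = 50,
                                    n_samples = 1000L, L_z = 200,
                                    seed = 1L, dt = 1) {
  if (n_samples < 2L) stop("'n_samples' must be >= 2")
  if (length(mean_P) != 3L) stop("'mean_P' must have three components")
  if (L_z <= 0) stop("'L_z' must be positive")
  df <- with_seed(seed, data.frame(
    time = (seq_len(n_samples) - 1) * dt,
    P_xx = stats::rnorm(n_samples, mean_P[1], sigma),
    P_yy = stats::rnorm(n_samples, mean_P[2], sigma),
    P_zz = stats::rnorm(n_samples, mean_P[3], sigma)
  ))
  gamma_true <- .BAR_ANGSTROM_TO_MN_PER_M * (L_z / 2) *
    (mean_P[3] - (mean_P[1] + mean_P[2]) / 2)
  structure(list(data = df, L_z = L_z), class = "pressure_trace",
            gamma_true = gamma_true, seed = seed)
}

#' Ground truth for a simulated droplet-freezing assay
#'
#' Describes the singular (site-specific) model: each droplet carries a
#' Poisson number of active sites with mean
#' lambda(T) = molecules_per_droplet * site_density_fn(T) +
#' background_rate_fn(T), and freezes at the warmest temperature at which
#' at least one site is active.
#'
#' @param site_density_fn Cumulative active sites per molecule as a
#'   function of temperature (deg C); must be non-negative and
#'   non-increasing in T.
#' @param molecules_per_droplet Substrate molecules per droplet (> 0).
#' @param background_rate_fn Cumulative background sites per droplet vs T.
#' @param T_start,T_end Cooling range (deg C, `T_start > T_end`).
#' @param cooling_rate Cooling rate (K/min); recorded metadata.
#' @param bin_width Measurement grid spacing (K).
#' @param n_droplets Number of droplets (>= 1).
#' @param seed RNG seed used by [simulate_freezing_assay()].
#' @return An object of class `assay_ground_truth`.
#' @export
assay_ground_truth <- function(site_density_fn, molecules_per_droplet,
                               background_rate_fn = function(T) rep(0, length(T)),
                               T_start = 0, T_end = -30, cooling_rate = 1,
                               bin_width = 0.5, n_droplets = 96L, seed = 1L) {
  if (n_droplets < 1L) stop("'n_droplets' must be >= 1")
  if (molecules_per_droplet <= 0) stop("'molecules_per_droplet' must be positive")
  if (T_end >= T_start) stop("'T_end' must be colder than 'T_start'")
  if (bin_width <= 0) stop("'bin_width' must be positive")
  grid <- seq(T_start, T_end, by = -bin_width)
  s <- site_density_fn(grid)
  if (any(!is.finite(s)) || any(s < 0)) {
    stop("'site_density_fn' must be finite and non-negative on the grid")
  }
  if (any(diff(s) < -1e-12)) {
    stop("'site_density_fn' must be non-increasing in temperature")
  }
  structure(
    list(site_density_fn = site_density_fn,
         molecules_per_droplet = molecules_per_droplet,
         background_rate_fn = background_rate_fn,
         T_start = T_start, T_end = T_end, cooling_rate = cooling_rate,
         bin_width = bin_width, n_droplets = as.integer(n_droplets),
         seed = seed),
    class = "assay_ground_truth"
  )
}

#' Simulate a cold-stage droplet-freezing assay
#'
#' Draws, per droplet and per temperature interval, a Poisson number of
#' newly active sites with mean equal to the increment of lambda(T) over
#' the interval; the droplet's freezing temperature is the warmest grid
#' temperature at which at least one site is active.  Droplets with no
#' active site by `T_end` are censored.  By construction the expected
#' fraction frozen obeys f(T) = 1 - exp(-lambda(T)).
#'
#' @param truth An [assay_ground_truth()].
#' @return An object of class `freezing_assay`: `droplets` (data frame
#'   `droplet_id`, `T_freeze` in deg C with `NA` for censored, `censored`),
#'   and `meta` (grid, molecules per droplet, cooling parameters, seed).
#'   The ground truth travels along as attribute `truth`.
#' @export
simulate_freezing_assay <- function(truth) {
  stopifnot(inherits(truth, "assay_ground_truth"))
  grid <- seq(truth$T_start, truth$T_end, by = -truth$bin_width)
  lam <- truth$molecules_per_droplet * truth$site_density_fn(grid) +
    truth$background_rate_fn(grid)
  if (any(diff(lam) < -1e-12)) {
    stop("cumulative site mean must be non-decreasing on cooling")
  }
  inc <- diff(c(0, lam))
  inc[inc < 0] <- 0
  n <- truth$n_droplets
  nb <- length(grid)
  T_freeze <- with_seed(truth$seed, {
    counts <- matrix(stats::rpois(n * nb, rep(inc, each = n)), n, nb)
    first <- apply(counts > 0L, 1L, function(r) {
      w <- which(r); if (length(w)) w[1L] else NA_integer_
    })
    grid[first]
  })
  droplets <- data.frame(
    droplet_id = seq_len(n),
    T_freeze = T_freeze,
    censored = is.na(T_freeze)
  )
  structure(
    list(droplets = droplets,
         meta = list(molecules_per_droplet = truth$molecules_per_droplet,
                     T_start = truth$T_start, T_end = truth$T_end,
                     cooling_rate = truth$cooling_rate,
                     bin_width = truth$bin_width,
                     n_droplets = n,
                     temperature_uncertainty = 0.2,
                     volume_uL = 30,
                     seed = truth$seed)),
    class = "freezing_assay", truth = truth
  )
}

#' Construct a freezing assay from droplet records
#'
#' @param droplets Data frame with columns `droplet_id`, `T_freeze`
#'   (deg C, `NA` when censored) and optionally `censored`.
#' @param molecules_per_droplet Substrate molecules per droplet.
#' @param T_start,T_end Cooling range (deg C).
#' @param cooling_rate Cooling rate (K/min).
#' @param bin_width Analysis bin width (K).
#' @return A `freezing_assay`.
#' @export
freezing_assay <- function(droplets, molecules_per_droplet,
                           T_start = 0, T_end = -30, cooling_rate = 1,
                           bin_width = 0.5) {
  if (!all(c("droplet_id", "T_freeze") %in% names(droplets))) {
    stop("'droplets' needs columns droplet_id and T_freeze")
  }
  if (!"censored" %in% names(droplets)) {
    droplets$censored <- is.na(droplets$T_freeze)
  }
  tf <- droplets$T_freeze[!droplets$censored]
  if (any(tf > T_start + 1e-9 | tf < T_end - 1e-9)) {
    stop("freezing temperatures must lie within [T_end, T_start]")
  }
  structure(
    list(droplets = droplets,
         meta = list(molecules_per_droplet = molecules_per_droplet,
                     T_start = T_start, T_end = T_end,
                     cooling_rate = cooling_rate, bin_width = bin_width,
                     n_droplets = nrow(droplets),
                     temperature_uncertainty = 0.2, volume_uL = NA_real_,
                     seed = NA_integer_)),
    class = "freezing_assay"
  )
}

#' Write / read assay droplet tables
#'
#' Delimited text with columns `droplet_id`, `T_freeze`, `censored`
#' (censored droplets carry an empty `T_freeze`), plus `# key: value`
#' metadata comment lines.
#'
#' @param assay A `freezing_assay`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_assay <- function(assay, path) {
  stopifnot(inherits(assay, "freezing_assay"))
  write_series(assay$droplets, path,
               meta = assay$meta[c("molecules_per_droplet", "T_start", "T_end",
                                   "cooling_rate", "bin_width")])
  invisible(path)
}

#' @rdname write_assay
#' @param molecules_per_droplet Override for the molecules-per-droplet
#'   metadata; defaults to the value stored in the file.
#' @export
read_assay <- function(path, molecules_per_droplet = NULL) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(paste0("#\\s*", key, ":"), meta_lines, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(trimws(sub(paste0(".*", key, ":"), "", m[1L])))
  }
  s <- read_series(path, columns = c("droplet_id", "T_freeze", "censored"))
  df <- s$data
  df$censored <- df$censored > 0 | is.na(df$T_freeze)
  freezing_assay(
    df,
    molecules_per_droplet = molecules_per_droplet %||%
      get_meta("molecules_per_droplet", 1),
    T_start = get_meta("T_start", 0),
    T_end = get_meta("T_end", -30),
    cooling_rate = get_meta("cooling_rate", 1),
    bin_width = get_meta("bin_width", 0.5)
  )
}
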