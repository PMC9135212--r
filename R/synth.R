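#' Simulation configuration
#'
#' Bundles the generative parameters shared by the panel and series
#' simulators. The latent-field precisions correspond to the spatial
#' (structured u, unstructured v), temporal (structured gamma,
#' unstructured phi) and space-time interaction (delta) effects of the
#' spatiotemporal model; `base_rate` scales expected counts as
#' population times rate; the trend and amplitude parameters drive the
#' seasonal monthly-series generator.
#'
#' @param grid_rows,grid_cols,n_components lattice geometry (see
#'   [make_lattice()]).
#' @param T_months number of time points simulated.
#' @param base_rate expected events per person per period (> 0).
#' @param population_range length-2 range of persons per area.
#' @param b0 intercept of the log-relative-risk surface (default 0).
#' @param trend_slope per-month change in the mean level of the monthly
#'   series generator.
#' @param amplitude_start,amplitude_slope seasonal amplitude at month 0
#'   and its per-month linear change.
#' @param phase seasonal phase in radians (peak month = 12 * phase / (2*pi)).
#' @param noise_sd Gaussian noise standard deviation for the series
#'   generator.
#' @param tau_u,tau_v,tau_gamma,tau_phi,tau_delta strictly positive
#'   precisions of the latent fields; large values (e.g. 1e12) give
#'   effectively zero fields. Note that the marginal variance of an RW2
#'   field at fixed precision grows roughly cubically with the window
#'   length, so `tau_gamma` is calibrated for the default six-year
#'   monthly window (field standard deviation about 0.3 on the log-risk
#'   scale) and should be rescaled for very different `T_months`.
#' @param interaction_type one of "none", "I", "II", "III".
#' @param allow_amplitude_flip logical; the amplitude line
#'   `amplitude_start + amplitude_slope * t` crossing zero inside the
#'   simulated window flips the seasonal phase, which must be opted into
#'   explicitly.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(grid_rows = 6L, grid_cols = 6L, n_components = 1L,
                       T_months = 72L, base_rate = 2e-4,
                       population_range = c(15000, 120000),
                       b0 = 0, trend_slope = -0.5,
                       amplitude_start = 20, amplitude_slope = -0.15,
                       phase = 2 * pi * 7 / 12, noise_sd = 3,
                       tau_u = 10, tau_v = 20, tau_gamma = 1e4, tau_phi = 50,
                       tau_delta = 50, interaction_type = "none",
                       allow_amplitude_flip = FALSE, seed = 1L) {
  cfg <- list(grid_rows = as.integer(grid_rows),
              grid_cols = as.integer(grid_cols),
              n_components = as.integer(n_components),
              T_months = as.integer(T_months), base_rate = base_rate,
              population_range = population_range, b0 = b0,
              trend_slope = trend_slope, amplitude_start = amplitude_start,
              amplitude_slope = amplitude_slope, phase = phase,
              noise_sd = noise_sd,
              tau_u = tau_u, tau_v = tau_v, tau_gamma = tau_gamma,
              tau_phi = tau_phi, tau_delta = tau_delta,
              interaction_type = match.arg(interaction_type,
                                           c("none", "I", "II", "III")),
              allow_amplitude_flip = isTRUE(allow_amplitude_flip),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  taus <- c(cfg$tau_u, cfg$tau_v, cfg$tau_gamma, cfg$tau_phi, cfg$tau_delta)
  if (any(!is.finite(taus)) || any(taus <= 0))
    stop("configuration error: all precisions must be strictly positive ",
         "and finite")
  if (cfg$base_rate <= 0)
    stop("configuration error: base_rate must be > 0")
  if (cfg$T_months < 1)
    stop("configuration error: T_months must be positive")
  a0 <- cfg$amplitude_start
  aT <- cfg$amplitude_start + cfg$amplitude_slope * (cfg$T_months - 1)
  if (a0 * aT < 0 && !cfg$allow_amplitude_flip)
    stop("seasonal amplitude crosses zero inside the simulated window ",
         "(phase flip); set allow_amplitude_flip = TRUE to permit this")
  invisible(cfg)
}

#' Read a simulation configuration from a YAML file
#'
#' Flat key-value YAML with the argument names of [sim_config()].
#'
#' @param path YAML file path.
#' @return `sim_config` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  vals <- yaml::read_yaml(path)
  do.call(sim_config, vals)
}

#' Simulate a spatiotemporal complaint panel with known latent truth
#'
#' Generates counts `y_it ~ Poisson(E_it * exp(eta_it))` on an areal
#' lattice, with `E_it = base_rate * population_i` and
#' `eta_it = b0 + u_i + v_i + gamma_t + phi_t + delta_it`. The structured
#' fields are exact constrained GMRF draws: u is ICAR on the contiguity
#' graph (sum-to-zero per component), gamma is RW2 (orthogonal to constant
#' and linear), delta follows the configured interaction structure, and v,
#' phi are iid Gaussian. The full latent truth is returned for recovery
#' tests.
#'
#' @param lattice an `area_lattice`.
#' @param config a `sim_config`.
#' @return list with `panel` (data.frame: `area_id`, `time`, `population`,
#'   `y`, `E`) and `truth` (list: `b0`, `u`, `v`, `gamma`, `phi`, `delta`
#'   (n x T), `eta` (n x T), `seed`).
#' @export
simulate_panel <- function(lattice, config) {
  stopifnot(inherits(lattice, "area_lattice"))
  validate_sim_config(config)
  n <- lattice$n_areas
  T <- config$T_months
  set.seed(config$seed)

  Qu <- icar_structure(lattice)
  u <- sample_gmrf(Qu, config$tau_u)
  v <- stats::rnorm(n, 0, 1 / sqrt(config$tau_v))
  if (T >= 4) {
    Qg <- rw2_structure(T)
    gamma <- sample_gmrf(Qg, config$tau_gamma)
  } else {
    gamma <- rep(0, T)
  }
  phi <- stats::rnorm(T, 0, 1 / sqrt(config$tau_phi))
  if (config$interaction_type == "none") {
    delta <- matrix(0, n, T)
  } else {
    st <- interaction_structure(config$interaction_type, lattice, T)
    delta <- matrix(sample_gmrf(st$Q, config$tau_delta), n, T)
  }

  eta <- config$b0 +
    matrix(u + v, n, T) +
    matrix(gamma + phi, n, T, byrow = TRUE) +
    delta
  E <- matrix(config$base_rate * lattice$areas$population, n, T)
  lambda <- E * exp(eta)
  if (any(!is.finite(lambda)) || any(lambda > 1e12)) {
    bad <- which(!is.finite(lambda) | lambda > 1e12, arr.ind = TRUE)[1, ]
    stop(sprintf("exp(eta) overflow at area %s, time %d",
                 lattice$areas$area_id[bad[1]], bad[2]))
  }
  y <- matrix(stats::rpois(n * T, lambda), n, T)

  panel <- data.frame(
    area_id = rep(lattice$areas$area_id, T),
    time = rep(seq_len(T), each = n),
    population = rep(lattice$areas$population, T),
    y = as.vector(y),
    E = as.vector(E),
    stringsAsFactors = FALSE
  )
  truth <- list(b0 = config$b0, u = u, v = v, gamma = gamma, phi = phi,
                delta = delta, eta = eta, seed = config$seed)
  list(panel = panel, truth = truth)
}

#' Simulate a monthly complaint series with seasonal amplitude drift
#'
#' Generates `y_t = level + trend_slope * t +
#' (amplitude_start + amplitude_slope * t) * cos(2*pi*t/12 - phase) +
#' Gaussian noise`, the generative counterpart of the harmonic trend model
#' with linearly varying amplitude. The seasonal period is fixed at 12
#' months.
#'
#' @param T number of months (24 or more recommended for identifiability;
#'   a warning is issued below that).
#' @param level mean level at month 0.
#' @param trend_slope per-month linear change in level.
#' @param amplitude_start,amplitude_slope seasonal amplitude at month 0
#'   and its per-month change.
#' @param phase phase in radians.
#' @param noise_sd non-negative Gaussian noise standard deviation.
#' @param seed integer seed.
#' @param label optional series label.
#' @return `monthly_series` data.frame with columns `t` (0-based month
#'   index) and `y`.
#' @export
simulate_monthly_series <- function(T, level, trend_slope = 0,
                                    amplitude_start = 0, amplitude_slope = 0,
                                    phase = 0, noise_sd = 0, seed = 1L,
                                    label = "simulated") {
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (T < 24) warning("T < 24: harmonic coefficients weakly identified")
  set.seed(as.integer(seed))
  t <- seq_len(T) - 1
  mu <- level + trend_slope * t +
    (amplitude_start + amplitude_slope * t) * cos(2 * pi * t / 12 - phase)
  y <- mu + stats::rnorm(T, 0, noise_sd)
  monthly_series(t = t, y = y, label = label)
}

#' Construct a monthly series object
#'
#' @param t integer month index, consecutive from its first value.
#' @param y numeric values (counts, rates or percentages).
#' @param denominator optional strictly positive parallel series (total
#'   inquiries or population) used for standardization when fitting.
#' @param label series label.
#' @return data.frame of class `monthly_series`.
#' @export
monthly_series <- function(t, y, denominator = NULL, label = "series") {
  t <- as.numeric(t)
  if (length(t) != length(y)) stop("'t' and 'y' lengths differ")
  if (length(t) > 1 && any(diff(t) != 1))
    stop("'t' must be strictly increasing with unit steps")
  df <- data.frame(t = t, y = as.numeric(y))
  if (!is.null(denominator)) {
    if (length(denominator) != length(y))
      stop("'denominator' must have the same length as 'y'")
    if (any(denominator <= 0))
      stop("'denominator' must be strictly positive")
    df$denominator <- as.numeric(denominator)
  }
  attr(df, "label") <- label
  class(df) <- c("monthly_series", "data.frame")
  df
}

#' Write / read a long-format panel CSV
#'
#' Columns: `area_id`, `time`, `population`, `y` and, when present, `E`.
#'
#' @param panel panel data.frame.
#' @param path file path.
#' @rdname panel_io
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(panel, path, row.names = FALSE)
  invisible(path)
}

#' @rdname panel_io
#' @export
read_panel <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
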