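# shared small fixtures, built in code at test time

toy_lattice_2x2 <- function(seed = 1) make_lattice(2, 2, seed = seed)

# a complete area x time panel with E filled, simulated under the null
null_panel <- function(lattice, T, b0 = 0, seed = 1) {
  cfg <- sim_config(grid_rows = 1, grid_cols = 2, T_months = T, b0 = b0,
                    tau_u = 1e12, tau_v = 1e12, tau_gamma = 1e12,
                    tau_phi = 1e12, interaction_type = "none", seed = seed)
  sim <- simulate_panel(lattice, cfg)
  sim$panel
}

# fake posterior object for pure-function tests of dic()/relative_risk()
fake_fit <- function(deviance, eta_mean, y, E, draws = NULL,
                     n = nrow(y), T = ncol(y)) {
  structure(list(deviance = deviance, eta_mean = eta_mean, y = y, E = E,
                 draws = draws, n = n, T = T,
                 area_ids = paste0("A", seq_len(n)), times = seq_len(T)),
            class = "st_posterior")
}

# write a small inquiries CSV and return its path
write_inquiry_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  writeLines(c("created_date,descriptor,complaint_type,area_id", rows), path)
  path
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

# seasonal series with no secular trend, for size/calibration checks
simulate_monthlies_null <- function(seed) {
  simulate_monthly_series(T = 60, level = 50, trend_slope = 0,
                          amplitude_start = 10, amplitude_slope = -0.05,
                          phase = 1.2, noise_sd = 5, seed = seed)
}
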