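#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# The study region is a two-component areal lattice (32 areas), mirroring
# an administrative geography whose contiguity graph is disconnected the
# way an island borough disconnects a city's neighbourhood graph. Six
# years of monthly complaint counts are simulated: a citywide monthly
# series with summer-peaking seasonality whose amplitude decays linearly
# and a declining secular trend, and an area x month Poisson panel with
# BYM spatial and RW2/IID temporal latent fields around
# population-proportional expected counts.

suppressPackageStartupMessages(library(pestsurv))

seed <- 20260901L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(grid_rows = 4, grid_cols = 4, n_components = 2,
                  T_months = 72, b0 = 0, trend_slope = -0.5,
                  amplitude_start = 20, amplitude_slope = -0.15,
                  phase = 2 * pi * 7 / 12, noise_sd = 3,
                  interaction_type = "none", seed = seed)
yaml::write_yaml(unclass(cfg), file.path(out, "config.yaml"))

lattice <- make_lattice(cfg$grid_rows, cfg$grid_cols, cfg$n_components,
                        cfg$population_range, seed = seed)
print(lattice)
write_adjacency(lattice, file.path(out, "adjacency.txt"))

sim <- simulate_panel(lattice, cfg)
write_panel(sim$panel, file.path(out, "panel_monthly.csv"))
utils::write.csv(
  data.frame(area_id = rep(lattice$areas$area_id, cfg$T_months),
             time = rep(seq_len(cfg$T_months), each = lattice$n_areas),
             eta = as.vector(sim$truth$eta)),
  file.path(out, "truth_eta.csv"), row.names = FALSE)

series <- simulate_monthly_series(cfg$T_months, level = 100,
                                  trend_slope = cfg$trend_slope,
                                  amplitude_start = cfg$amplitude_start,
                                  amplitude_slope = cfg$amplitude_slope,
                                  phase = cfg$phase, noise_sd = cfg$noise_sd,
                                  seed = seed + 1L, label = "citywide")
utils::write.csv(series, file.path(out, "series_citywide.csv"),
                 row.names = FALSE)

cat(sprintf("simulated %d areas x %d months; total events %d\n",
            lattice$n_areas, cfg$T_months, sum(sim$panel$y)))
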