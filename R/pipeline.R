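#' Run the full surveillance analysis pipeline on synthetic data
#'
#' Executes the complete chain: simulate a lattice and a monthly
#' complaint panel, fit the harmonic trend model to the citywide monthly
#' series and to each sub-lattice (borough-like component), aggregate the
#' panel to years and compute expected counts and SIRs, fit the
#' spatiotemporal model for each requested interaction type, compare the
#' fits by DIC, and export the relative-risk surface of the selected
#' model. All outputs are CSV; a JSON manifest records the inputs, the
#' config hash, the seed and the package version. Every source of
#' randomness derives from `seed`, so a repeated run is bit-identical.
#'
#' @param config a `sim_config` (its `seed` is overridden by `seed`).
#' @param out_dir output directory, created if absent.
#' @param seed integer master seed.
#' @param interaction_types character vector of interaction types to fit
#'   and compare.
#' @param n_iter,n_burn,thin MCMC controls passed to every fit.
#' @return (invisibly) list with the artifact paths, the comparison
#'   table, the trend report and the exit `status` (0 success, 1 a model
#'   stage failed).
#' @export
run_pipeline <- function(config = sim_config(), out_dir, seed = 1L,
                         interaction_types = c("I", "II", "III"),
                         n_iter = 4000L, n_burn = 1500L, thin = 2L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- as.integer(seed)
  paths <- list()

  # stage 1: simulate
  lattice <- make_lattice(config$grid_rows, config$grid_cols,
                          config$n_components, config$population_range,
                          seed = seed)
  sim <- simulate_panel(lattice, config)
  paths$panel <- file.path(out_dir, "panel_monthly.csv")
  write_panel(sim$panel, paths$panel)
  paths$adjacency <- file.path(out_dir, "adjacency.txt")
  write_adjacency(lattice, paths$adjacency)
  truth_df <- data.frame(area_id = rep(lattice$areas$area_id, config$T_months),
                         time = rep(seq_len(config$T_months),
                                    each = lattice$n_areas),
                         eta = as.vector(sim$truth$eta),
                         delta = as.vector(sim$truth$delta))
  paths$truth <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth_df, paths$truth, row.names = FALSE)

  # stage 2: harmonic trend fits, citywide and per component
  series <- list(citywide = simulate_monthly_series(
    T = config$T_months, level = 100, trend_slope = config$trend_slope,
    amplitude_start = config$amplitude_start,
    amplitude_slope = config$amplitude_slope, phase = config$phase,
    noise_sd = config$noise_sd, seed = seed + 1L, label = "citywide"))
  for (c_i in seq_len(lattice$n_components)) {
    ids <- lattice$areas$area_id[lattice$areas$component == c_i]
    sub <- sim$panel[sim$panel$area_id %in% ids, ]
    yt <- tapply(sub$y, sub$time, sum)
    series[[paste0("component_", c_i)]] <-
      monthly_series(t = as.numeric(names(yt)) - 1, y = as.numeric(yt),
                     label = paste0("component_", c_i))
  }
  report <- trend_report(series)
  paths$trend <- file.path(out_dir, "trend_report.csv")
  utils::write.csv(report, paths$trend, row.names = FALSE)
  resid <- do.call(rbind, lapply(names(series), function(nm) {
    f <- fit_harmonic_trend(series[[nm]])
    data.frame(series = nm, t = f$t, residual = f$residuals)
  }))
  paths$residuals <- file.path(out_dir, "trend_residuals.csv")
  utils::write.csv(resid, paths$residuals, row.names = FALSE)

  # stage 3: yearly panel, expected counts, SIR
  yearly <- aggregate_panel_years(sim$panel)
  yearly <- expected_counts(yearly, stratify_by_period = TRUE)
  yearly <- sir(yearly)
  paths$sir <- file.path(out_dir, "sir_yearly.csv")
  utils::write.csv(yearly, paths$sir, row.names = FALSE)

  # stage 4: spatiotemporal fits and DIC comparison
  status <- 0L
  if (length(interaction_types)) {
    specs <- lapply(seq_along(interaction_types), function(k)
      st_model_spec(interaction_types[k], n_iter = n_iter, n_burn = n_burn,
                    thin = thin, seed = seed + 17L * k))
    names(specs) <- paste0("Model ", interaction_types)
    ypanel <- yearly
    names(ypanel)[names(ypanel) == "year"] <- "time"
    cmp <- compare_models(ypanel, lattice, specs)
    status <- cmp$status
    paths$comparison <- file.path(out_dir, "model_comparison.csv")
    utils::write.csv(cmp$table, paths$comparison, row.names = FALSE)
    best <- cmp$fits[[cmp$selected]]
    paths$summary <- file.path(out_dir, "posterior_summary.csv")
    utils::write.csv(summary(best), paths$summary, row.names = FALSE)
    paths$deviance <- file.path(out_dir, "deviance_trace.csv")
    utils::write.csv(data.frame(draw = seq_along(best$deviance),
                                deviance = best$deviance),
                     paths$deviance, row.names = FALSE)
    rr <- relative_risk(best, mode = "interaction")
    rr_full <- relative_risk(best, mode = "full")
    rr_long <- data.frame(area_id = rep(rownames(rr), ncol(rr)),
                          time = rep(colnames(rr), each = nrow(rr)),
                          rr_interaction = as.vector(rr),
                          rr_full = as.vector(rr_full))
    paths$rr <- file.path(out_dir, "relative_risk.csv")
    utils::write.csv(rr_long, paths$rr, row.names = FALSE)
  } else {
    cmp <- NULL
  }

  # manifest
  paths$config <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(config), paths$config)
  manifest <- list(seed = as.integer(seed),
                   config_hash = unname(tools::md5sum(paths$config)),
                   package_version = as.character(
                     utils::packageVersion("pestsurv")),
                   interaction_types = interaction_types,
                   inputs = "synthetic (generated in stage 1)",
                   artifacts = lapply(paths, basename),
                   status = status)
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(paths = paths, comparison = cmp, trend_report = report,
                 lattice = lattice, status = status))
}

#' Aggregate a monthly panel to calendar years
#'
#' Sums observed counts over blocks of 12 consecutive months; the
#' population column is carried through unchanged (it is constant within
#' an area).
#'
#' @param panel monthly panel with columns `area_id`, `time` (1-based
#'   month), `population`, `y`.
#' @return yearly panel with columns `area_id`, `year`, `population`,
#'   `y`.
#' @export
aggregate_panel_years <- function(panel) {
  yr <- (panel$time - 1) %/% 12 + 1
  key <- paste(panel$area_id, yr, sep = "\r")
  y <- tapply(panel$y, key, sum)
  pop <- tapply(panel$population, key, mean)
  parts <- strsplit(names(y), "\r", fixed = TRUE)
  out <- data.frame(area_id = vapply(parts, `[[`, "", 1),
                    year = as.integer(vapply(parts, `[[`, "", 2)),
                    population = as.numeric(pop), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  out[order(out$year, out$area_id), ]
}
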