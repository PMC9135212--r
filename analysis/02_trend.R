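#!/usr/bin/env Rscript
# Stage 2: harmonic trend modelling of the monthly series.
#
# Fits the six-coefficient harmonic linear model (intercept, trend,
# sin/cos, t*sin/t*cos) to the citywide series and to each lattice
# component's aggregated counts, reports the secular-trend test and the
# seasonal amplitude at the first and last month, and runs the
# concordance regression between two simulated reporting streams.

suppressPackageStartupMessages(library(pestsurv))

data_dir <- "results/data"
out <- "results"
stopifnot(file.exists(file.path(data_dir, "panel_monthly.csv")))

citywide <- utils::read.csv(file.path(data_dir, "series_citywide.csv"))
panel <- read_panel(file.path(data_dir, "panel_monthly.csv"))

series <- list(citywide = monthly_series(citywide$t, citywide$y,
                                         label = "citywide"))
lattice <- read_adjacency(file.path(data_dir, "adjacency.txt"))
for (c_i in sort(unique(lattice$areas$component))) {
  ids <- lattice$areas$area_id[lattice$areas$component == c_i]
  sub <- panel[panel$area_id %in% ids, ]
  yt <- tapply(sub$y, sub$time, sum)
  series[[paste0("component_", c_i)]] <-
    monthly_series(as.numeric(names(yt)) - 1, as.numeric(yt))
}

report <- trend_report(series)
utils::write.csv(report, file.path(out, "trend_report.csv"),
                 row.names = FALSE)
print(report[, c("series", "beta_trend", "trend_p", "r_squared",
                 "amplitude_first", "amplitude_last", "trend")])
cat("\nThe citywide series shows a", report$trend[1],
    "secular trend with the seasonal amplitude shrinking from",
    round(report$amplitude_first[1], 1), "to",
    round(report$amplitude_last[1], 1), "events.\n")

# concordance between owner-mandated reports (complete counts) and
# resident complaints (60% detection per infestation)
set.seed(20260902L)
owner <- rpois(50, 120)
complaints <- rbinom(50, owner, 0.6)
conc <- concordance_regression(owner, complaints)
utils::write.csv(data.frame(slope = conc$slope, lo = conc$slope_ci[1],
                            hi = conc$slope_ci[2],
                            r_squared = conc$r_squared, p = conc$p),
                 file.path(out, "concordance.csv"), row.names = FALSE)
cat(sprintf("concordance slope %.2f (95%% CI %.2f-%.2f), R^2 = %.2f\n",
            conc$slope, conc$slope_ci[1], conc$slope_ci[2],
            conc$r_squared))
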