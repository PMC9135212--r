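test_that("rook lattices have the hand-enumerated degree structure", {
  # smallest graph: a 1x2 path
  lat <- quiet(make_lattice(1, 2, seed = 1))
  expect_equal(lat$n_areas, 2)
  expect_equal(unname(rowSums(lat$adj)), c(1, 1))
  expect_equal(sum(lat$adj) / 2, 1)

  # 3x3: corners degree 2, edge midpoints 3, centre 4 (row-major order)
  lat9 <- quiet(make_lattice(3, 3, seed = 1))
  expect_equal(unname(rowSums(lat9$adj)), c(2, 3, 2, 3, 4, 3, 2, 3, 2))

  # two disconnected 2x2 components: block-diagonal adjacency
  lat8 <- make_lattice(2, 2, n_components = 2, seed = 1)
  expect_equal(lat8$n_areas, 8)
  block <- matrix(c(0, 1, 1, 0,
                    1, 0, 0, 1,
                    1, 0, 0, 1,
                    0, 1, 1, 0), 4, 4)
  expected <- matrix(0L, 8, 8)
  expected[1:4, 1:4] <- block
  expected[5:8, 5:8] <- block
  expect_equal(unname(lat8$adj), expected)
  expect_equal(lat8$areas$component, rep(1:2, each = 4))

  expect_error(make_lattice(0, 3), "positive")
  expect_error(make_lattice(1, 1), "at least 2")
})

test_that("populations respect the configured range and seed", {
  lat <- make_lattice(3, 4, population_range = c(100, 200), seed = 9)
  expect_true(all(lat$areas$population >= 100 & lat$areas$population <= 200))
  lat2 <- make_lattice(3, 4, population_range = c(100, 200), seed = 9)
  expect_identical(lat$areas$population, lat2$areas$population)
})

test_that("sample_gmrf draws live in the constraint space", {
  lat <- make_lattice(2, 2, n_components = 2, seed = 1)
  Q <- icar_structure(lat)
  x <- sample_gmrf(Q, tau = 1, seed = 3)
  comp <- lat$areas$component
  expect_lt(max(abs(tapply(x, comp, sum))), 1e-10)

  # degenerate limit: huge precision pins the field to zero
  x0 <- sample_gmrf(Q, tau = 1e12, seed = 4)
  expect_lt(max(abs(x0)), 1e-4)

  # 2-node path: sum-to-zero forces exact negatives
  path2 <- quiet(make_lattice(1, 2, seed = 1))
  xp <- sample_gmrf(icar_structure(path2), tau = 1, seed = 5)
  expect_equal(xp[1], -xp[2])

  # RW2 draws are orthogonal to constant and linear vectors
  Qg <- rw2_structure(12)
  g <- sample_gmrf(Qg, tau = 2, seed = 6)
  expect_lt(abs(sum(g)), 1e-10)
  expect_lt(abs(sum(seq_along(g) * g)), 1e-9)

  expect_error(sample_gmrf(matrix(c(0, 1, 0, 0), 2, 2), 1), "symmetric")
})

test_that("sample_gmrf covariance matches the pseudo-inverse oracle", {
  lat <- quiet(make_lattice(3, 3, seed = 1))
  Q <- unclass(icar_structure(lat))
  attributes(Q)[c("rank", "components")] <- NULL
  tau <- 2
  set.seed(42)
  draws <- t(replicate(20000, sample_gmrf(Q, tau)))
  emp <- cov(draws)
  target <- MASS::ginv(tau * Q)
  rel_err <- norm(emp - target, "F") / norm(target, "F")
  expect_lt(rel_err, 0.05)
})

test_that("simulate_panel obeys the null model and conservation", {
  lat <- make_lattice(6, 6, seed = 2)
  cfg <- sim_config(grid_rows = 6, grid_cols = 6, T_months = 24, b0 = 0,
                    tau_u = 1e12, tau_v = 1e12, tau_gamma = 1e12,
                    tau_phi = 1e12, interaction_type = "none", seed = 11)
  sim <- simulate_panel(lat, cfg)
  # y/E centred at 1 within 3 Monte-Carlo standard errors
  ratio <- sim$panel$y / sim$panel$E
  mc_se <- sd(ratio) / sqrt(length(ratio))
  expect_lt(abs(mean(ratio) - 1), 3 * mc_se)
  # interaction "none" means delta is identically zero
  expect_true(all(sim$truth$delta == 0))
  # conservation: recorded eta equals the sum of stored components exactly
  n <- lat$n_areas; T <- cfg$T_months
  eta2 <- cfg$b0 + matrix(sim$truth$u + sim$truth$v, n, T) +
    matrix(sim$truth$gamma + sim$truth$phi, n, T, byrow = TRUE) +
    sim$truth$delta
  expect_identical(sim$truth$eta, eta2)
})

test_that("simulate_panel is a pure function of (inputs, seed)", {
  lat <- make_lattice(6, 6, seed = 2)
  cfg <- sim_config(grid_rows = 6, grid_cols = 6, T_months = 24, seed = 7)
  s1 <- simulate_panel(lat, cfg)
  s2 <- simulate_panel(lat, cfg)
  expect_identical(s1$panel, s2$panel)
  expect_identical(s1$truth, s2$truth)
})

test_that("interaction fields carry the configured structure", {
  lat <- toy_lattice_2x2()
  for (ty in c("I", "II", "III")) {
    cfg <- sim_config(grid_rows = 2, grid_cols = 2, T_months = 6,
                      interaction_type = ty, tau_delta = 4, seed = 8)
    sim <- simulate_panel(lat, cfg)
    expect_false(all(sim$truth$delta == 0))
    if (ty == "II")  # per-area rows orthogonal to constant and linear
      expect_lt(max(abs(rowSums(sim$truth$delta))), 1e-9)
    if (ty == "III") # per-period columns sum to zero
      expect_lt(max(abs(colSums(sim$truth$delta))), 1e-9)
  }
})

test_that("exp(eta) overflow is reported with the offending cell", {
  lat <- quiet(make_lattice(1, 2, seed = 1))
  cfg <- sim_config(grid_rows = 1, grid_cols = 2, T_months = 4, b0 = 60,
                    tau_u = 1e12, tau_v = 1e12, tau_gamma = 1e12,
                    tau_phi = 1e12, interaction_type = "none", seed = 1)
  expect_error(simulate_panel(lat, cfg), "overflow at area A001, time 1")
})

test_that("null counts are Poisson-dispersed (variance-to-mean near 1)", {
  # equal populations so cells share one mean and pooling is meaningful
  lat <- make_lattice(6, 6, population_range = c(50000, 50000), seed = 3)
  cfg <- sim_config(grid_rows = 6, grid_cols = 6, T_months = 144, b0 = 0,
                    amplitude_slope = 0,
                    population_range = c(50000, 50000),
                    tau_u = 1e12, tau_v = 1e12, tau_gamma = 1e12,
                    tau_phi = 1e12, interaction_type = "none", seed = 13)
  sim <- simulate_panel(lat, cfg)
  expect_gte(nrow(sim$panel), 5000)
  vmr <- var(sim$panel$y) / mean(sim$panel$y)
  expect_gt(vmr, 0.9)
  expect_lt(vmr, 1.1)
})

test_that("the monthly series generator matches its closed form", {
  # no seasonality, no noise: an exact straight line
  s <- simulate_monthly_series(36, level = 10, trend_slope = 2, seed = 1)
  expect_equal(s$y, 10 + 2 * s$t, tolerance = 1e-12)
  # cosine at t = 0 with zero phase adds exactly the starting amplitude
  s2 <- simulate_monthly_series(24, level = 5, amplitude_start = 7,
                                phase = 0, seed = 1)
  expect_equal(s2$y[1] - 5, 7, tolerance = 1e-12)
  expect_error(simulate_monthly_series(24, 1, noise_sd = -1), "non-negative")
  expect_warning(simulate_monthly_series(12, 1), "T < 24")
})

test_that("amplitude sign flips must be explicitly allowed", {
  expect_error(
    sim_config(T_months = 72, amplitude_start = 5, amplitude_slope = -0.5),
    "allow_amplitude_flip")
  cfg <- sim_config(T_months = 72, amplitude_start = 5,
                    amplitude_slope = -0.5, allow_amplitude_flip = TRUE)
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(tau_u = 0), "strictly positive")
})

test_that("panel and adjacency files round-trip", {
  lat <- make_lattice(2, 2, n_components = 2, seed = 4)
  cfg <- sim_config(grid_rows = 2, grid_cols = 2, n_components = 2,
                    T_months = 6, seed = 5)
  sim <- simulate_panel(lat, cfg)
  pf <- tempfile(fileext = ".csv")
  write_panel(sim$panel, pf)
  back <- read_panel(pf)
  expect_equal(back$y, sim$panel$y)
  expect_equal(back$E, sim$panel$E, tolerance = 1e-12)

  af <- tempfile(fileext = ".txt")
  write_adjacency(lat, af)
  lat2 <- read_adjacency(af)
  expect_identical(unname(lat2$adj == 1), unname(lat$adj == 1))
  expect_equal(lat2$n_components, lat$n_components)
})
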