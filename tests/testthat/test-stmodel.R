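test_that("ICAR structure is the graph Laplacian with component null space", {
  path2 <- quiet(make_lattice(1, 2, seed = 1))
  Q <- icar_structure(path2)
  expect_equal(unname(unclass(Q))[1:2, 1:2], matrix(c(1, -1, -1, 1), 2, 2))

  lat9 <- quiet(make_lattice(3, 3, seed = 1))
  Q9 <- icar_structure(lat9)
  expect_equal(qr(Q9)$rank, 8)
  expect_lt(max(abs(Q9 %*% rep(1, 9))), 1e-12)

  lat2c <- make_lattice(2, 2, n_components = 2, seed = 1)
  Q2 <- icar_structure(lat2c)
  expect_equal(qr(Q2)$rank, 6)
  expect_equal(attr(Q2, "rank"), 6)

  # isolated node: its own component, logged
  adj <- matrix(0, 3, 3)
  adj[1, 2] <- adj[2, 1] <- 1
  expect_message(icar_structure(adj), "isolated")
})

test_that("RW2 structure annihilates constants and lines", {
  Q4 <- rw2_structure(4)
  expect_lt(max(abs(Q4 %*% rep(1, 4))), 1e-12)
  expect_lt(max(abs(Q4 %*% (0:3))), 1e-12)
  Q5 <- rw2_structure(5)
  expect_equal(unname(Q5[3, ]), c(1, -4, 6, -4, 1))
  expect_gt(min(eigen(rw2_structure(9), symmetric = TRUE)$values), -1e-10)
  expect_equal(attr(Q5, "rank"), 3)
  expect_error(rw2_structure(3), "T >= 4")
})

test_that("interaction structures have the Kronecker ranks", {
  lat4 <- toy_lattice_2x2()
  stI <- interaction_structure("I", lat4, 3)
  expect_equal(stI$Q, diag(12))
  expect_equal(stI$rank, 12)

  lat2 <- quiet(make_lattice(1, 2, seed = 1))
  stII <- interaction_structure("II", lat2, 4)
  expect_equal(stII$rank, 2 * (4 - 2))
  expect_equal(qr(stII$Q)$rank, stII$rank)

  lat9 <- quiet(make_lattice(3, 3, seed = 1))
  stIII <- interaction_structure("III", lat9, 2)
  expect_equal(stIII$rank, 2 * 8)
  expect_equal(qr(stIII$Q)$rank, stIII$rank)

  expect_error(interaction_structure("none", lat4, 4), "none")
})

test_that("conjugate precision update matches the closed form", {
  # 1-d case: x ~ N(0, 1/tau), Gamma(a, b) prior
  pp <- precision_posterior(field = 1.7, Q = matrix(1), rank = 1,
                            shape = 2, rate = 0.5)
  expect_equal(pp$shape, 2.5)
  expect_equal(pp$rate, 0.5 + 1.7^2 / 2)

  # ICAR case against an explicit edge-difference sum
  lat <- toy_lattice_2x2()
  Q <- icar_structure(lat)
  x <- c(0.3, -0.1, 0.2, -0.4)
  pp2 <- precision_posterior(x, Q, rank = 3, shape = 1, rate = 5e-4)
  edges <- which(lat$adj == 1 & upper.tri(lat$adj), arr.ind = TRUE)
  quad <- sum((x[edges[, 1]] - x[edges[, 2]])^2)
  expect_equal(pp2$rate, 5e-4 + quad / 2, tolerance = 1e-12)
  expect_equal(pp2$shape, 1 + 1.5)
})

test_that("log posterior is linear in y and finite on finite states", {
  lat <- toy_lattice_2x2()
  panel <- expected_counts(null_panel(lat, 4), stratify_by_period = FALSE)
  spec <- st_model_spec("I", n_iter = 100, n_burn = 50)
  state <- list(b0 = 0.2, u = c(0.1, -0.1, 0.05, -0.05),
                v = c(0.02, 0.01, -0.02, -0.01),
                gamma = c(0.1, -0.05, -0.1, 0.05),
                phi = c(0.01, -0.01, 0.02, -0.02),
                delta = matrix(0.03, 4, 4),
                tau = c(u = 2, v = 3, gamma = 4, phi = 5, delta = 6))
  lp1 <- log_posterior_st(state, panel, lat, spec)
  expect_true(is.finite(lp1))

  # doubling y changes only the sum(y * eta) term
  n <- 4; T <- 4
  eta <- state$b0 + matrix(state$u + state$v, n, T) +
    matrix(state$gamma + state$phi, n, T, byrow = TRUE) + state$delta
  m <- panel
  m2 <- panel; m2$y <- 2 * m2$y
  lp2 <- log_posterior_st(state, m2, lat, spec)
  ids <- lat$areas$area_id
  ymat <- matrix(panel$y[order(panel$time, match(panel$area_id, ids))], n, T)
  expect_equal(lp2 - lp1, sum(ymat * eta), tolerance = 1e-8)

  state$tau[1] <- -1
  expect_error(suppressWarnings(log_posterior_st(state, panel, lat, spec)),
               "non-finite")
})

test_that("fixed seeds give bit-identical fits and summaries", {
  lat <- toy_lattice_2x2()
  panel <- null_panel(lat, 6, b0 = log(2), seed = 5)
  spec <- st_model_spec("I", n_iter = 600, n_burn = 200, thin = 2, seed = 99)
  f1 <- fit_st_model(panel, lat, spec)
  f2 <- fit_st_model(panel, lat, spec)
  expect_identical(f1$draws, f2$draws)
  expect_identical(summary(f1), summary(f2))
})

test_that("stored deviance matches recomputation from the draw matrices", {
  lat <- toy_lattice_2x2()
  panel <- null_panel(lat, 6, b0 = log(2), seed = 6)
  spec <- st_model_spec("I", n_iter = 500, n_burn = 300, thin = 1, seed = 3)
  fit <- fit_st_model(panel, lat, spec)
  n <- fit$n; T <- fit$T
  for (s in c(1, 50, length(fit$draws$b0))) {
    eta_s <- fit$draws$b0[s] +
      matrix(fit$draws$u[s, ] + fit$draws$v[s, ], n, T) +
      matrix(fit$draws$gamma[s, ] + fit$draws$phi[s, ], n, T, byrow = TRUE) +
      matrix(fit$draws$delta[s, ], n, T)
    dev_s <- -2 * sum(dpois(fit$y, fit$E * exp(eta_s), log = TRUE))
    expect_equal(fit$deviance[s], dev_s, tolerance = 1e-8)
  }
})

test_that("every retained draw satisfies the sum-to-zero constraints", {
  lat <- make_lattice(2, 2, n_components = 2, seed = 2)
  cfg <- sim_config(grid_rows = 2, grid_cols = 2, n_components = 2,
                    T_months = 6, b0 = log(2), tau_u = 1e12, tau_v = 1e12,
                    tau_gamma = 1e12, tau_phi = 1e12,
                    interaction_type = "none", seed = 4)
  panel <- expected_counts(simulate_panel(lat, cfg)$panel,
                           stratify_by_period = FALSE)
  spec <- st_model_spec("III", n_iter = 600, n_burn = 200, thin = 2, seed = 8)
  fit <- fit_st_model(panel, lat, spec)
  expect_lt(max(fit$constraint_resid), 1e-8)
  comp <- lat$areas$component
  S <- length(fit$draws$b0)
  tvec <- seq_len(fit$T) - (fit$T + 1) / 2
  for (s in c(1, S %/% 2, S)) {
    expect_lt(max(abs(tapply(fit$draws$u[s, ], comp, sum))), 1e-8)
    expect_lt(abs(sum(fit$draws$gamma[s, ])), 1e-8)
    expect_lt(abs(sum(tvec * fit$draws$gamma[s, ])), 1e-8)
    del <- matrix(fit$draws$delta[s, ], fit$n, fit$T)
    expect_lt(max(abs(apply(del, 2, function(col) tapply(col, comp, sum)))),
              1e-8)
  }
})

test_that("DIC reduces to the deviance for a degenerate posterior", {
  y <- matrix(c(3, 1, 4, 2), 2, 2)
  E <- matrix(2, 2, 2)
  eta0 <- matrix(0.1, 2, 2)
  D <- -2 * sum(dpois(y, E * exp(eta0), log = TRUE))
  fit <- fake_fit(deviance = rep(D, 25), eta_mean = eta0, y = y, E = E)
  out <- dic(fit)
  expect_equal(out$p_d, 0, tolerance = 1e-10)
  expect_equal(out$dic, D, tolerance = 1e-10)
  expect_error(dic(fake_fit(rep(D, 5), eta0, y, E)), "fewer than 10")
})

test_that("a richer nested model does not fit worse in mean deviance", {
  lat <- toy_lattice_2x2()
  cfg <- sim_config(grid_rows = 2, grid_cols = 2, T_months = 8, b0 = log(3),
                    tau_u = 4, tau_v = 4, tau_gamma = 16, tau_phi = 16,
                    interaction_type = "I", tau_delta = 4, seed = 12)
  panel <- expected_counts(simulate_panel(lat, cfg)$panel,
                           stratify_by_period = FALSE)
  simple <- fit_st_model(panel, lat,
    st_model_spec("none", n_iter = 2000, n_burn = 800, seed = 5))
  rich <- fit_st_model(panel, lat,
    st_model_spec("I", n_iter = 2000, n_burn = 800, seed = 5))
  # allow Monte-Carlo slack of 3 combined standard errors
  se <- sqrt(var(simple$deviance) / length(simple$deviance) +
             var(rich$deviance) / length(rich$deviance))
  expect_lt(rich$dic$d_bar, simple$dic$d_bar + 3 * se)
})

test_that("relative risk surfaces follow the draws", {
  y <- matrix(1, 2, 2); E <- matrix(1, 2, 2)
  draws <- list(b0 = c(0, 0), delta = matrix(0, 2, 4),
                u = matrix(0, 2, 2), v = matrix(0, 2, 2),
                gamma = matrix(0, 2, 2), phi = matrix(0, 2, 2))
  fit <- fake_fit(rep(1, 10), matrix(0, 2, 2), y, E, draws = draws)
  expect_true(all(relative_risk(fit, "interaction") == 1))

  draws1 <- draws
  draws1$b0 <- 0
  draws1$delta <- matrix(c(log(2), 0, 0, 0), 1, 4)
  draws1$u <- matrix(0, 1, 2); draws1$v <- matrix(0, 1, 2)
  draws1$gamma <- matrix(0, 1, 2); draws1$phi <- matrix(0, 1, 2)
  fit1 <- fake_fit(rep(1, 10), matrix(0, 2, 2), y, E, draws = draws1)
  expect_equal(relative_risk(fit1, "interaction")[1, 1], 2)

  # Jensen: mean of exp over a dispersed trace exceeds exp of the mean
  set.seed(9)
  dd <- matrix(rnorm(200, 0, 1), 50, 4)
  fitJ <- fake_fit(rep(1, 50), matrix(0, 2, 2), y, E,
                   draws = modifyList(draws, list(delta = dd)))
  rrJ <- relative_risk(fitJ, "interaction")
  expect_true(all(rrJ >= exp(matrix(colMeans(dd), 2, 2))))

  fit_none <- fake_fit(rep(1, 10), matrix(0, 2, 2), y, E,
                       draws = modifyList(draws, list(delta = NULL)))
  expect_error(relative_risk(fit_none, "interaction"), "none")
})

test_that("model ranking flags ties and prefers parsimony on them", {
  tab <- rank_models(c(100.0, 100.4, 130), p_d = c(12, 8, 20),
                     labels = c("A", "B", "C"))
  expect_true(all(tab$tie[1:2]))
  expect_false(tab$tie[3])
  expect_equal(attr(tab, "selected"), "B")  # smaller p_d wins the tie
  expect_equal(tab$model, c("A", "B", "C"))
  expect_error(rank_models(100), "at least 2")
})

test_that("comparison survives a failing fit and records it", {
  lat <- toy_lattice_2x2()
  panel <- null_panel(lat, 6, b0 = log(2), seed = 7)
  good <- st_model_spec("I", n_iter = 400, n_burn = 150, seed = 2)
  good2 <- st_model_spec("none", n_iter = 400, n_burn = 150, seed = 2)
  bad <- structure(list(), class = "st_model_spec")
  cmp <- compare_models(panel, lat, list(A = good, B = bad, C = good2))
  expect_equal(cmp$status, 1L)
  expect_length(cmp$failures, 1)
  expect_equal(nrow(cmp$table), 2)

  # two identical specifications tie
  cmp2 <- compare_models(panel, lat, list(A = good, B = good))
  expect_true(all(cmp2$table$tie))
})

test_that("prior-only sampling reproduces the hyperprior mean of each precision", {
  lat <- quiet(make_lattice(1, 2, seed = 1))
  panel <- expected_counts(null_panel(lat, 4), stratify_by_period = FALSE)
  spec <- st_model_spec("I", prior_shape = 1, prior_rate = 5e-4,
                        n_iter = 51000, n_burn = 1000, thin = 1, seed = 42)
  ch <- fit_st_model(panel, lat, spec, prior_only = TRUE)
  means <- colMeans(ch$draws$tau)
  expect_equal(nrow(ch$draws$tau), 50000)
  for (m in means) expect_lt(abs(m - 2000) / 2000, 0.05)
})

test_that("alternative hyperpriors run and shift the precision posterior", {
  lat <- toy_lattice_2x2()
  panel <- null_panel(lat, 6, b0 = log(2), seed = 10)
  f1 <- fit_st_model(panel, lat,
    st_model_spec("none", prior_shape = 1, prior_rate = 5e-4,
                  n_iter = 600, n_burn = 200, seed = 3))
  f2 <- fit_st_model(panel, lat,
    st_model_spec("none", prior_shape = 0.5, prior_rate = 5e-4,
                  n_iter = 600, n_burn = 200, seed = 3))
  expect_true(is.finite(f1$dic$dic) && is.finite(f2$dic$dic))
  expect_false(identical(f1$draws$tau, f2$draws$tau))
})

test_that("multiple chains yield potential scale reduction diagnostics", {
  lat <- toy_lattice_2x2()
  panel <- null_panel(lat, 6, b0 = log(2), seed = 11)
  spec <- st_model_spec("none", n_iter = 1200, n_burn = 400, thin = 2,
                        n_chains = 2, seed = 6)
  fit <- fit_st_model(panel, lat, spec)
  expect_false(is.null(fit$rhat))
  expect_true(all(is.finite(fit$rhat)))
  expect_lt(fit$rhat[["b0"]], 1.2)
})

test_that("posterior quantile ordering holds for every scalar summary", {
  lat <- toy_lattice_2x2()
  panel <- null_panel(lat, 6, b0 = log(2), seed = 13)
  fit <- fit_st_model(panel, lat,
    st_model_spec("I", n_iter = 800, n_burn = 300, seed = 21))
  sm <- summary(fit)
  expect_true(all(sm$q025 <= sm$mean + 1e-12))
  expect_true(all(sm$mean <= sm$q975 + 1e-12))
})
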