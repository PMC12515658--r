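test_that("doubling/halving times convert to rates as log(2)/time", {
  expect_equal(rate_from_time(log(2)), 1.0)
  expect_equal(rate_from_time(14), log(2) / 14)
  expect_error(rate_from_time(0), "positive")
  expect_error(rate_from_time(-3), "positive")
})

test_that("density switch is the Beta(3,1) CDF with saturation above 1", {
  expect_identical(delta_switch(0), 0)
  expect_identical(delta_switch(1), 1)
  expect_equal(delta_switch(0.5), 0.125)
  expect_identical(delta_switch(1.7), 1)   # transient overshoot saturates
  u <- seq(0, 1.5, by = 0.01)
  expect_true(all(diff(delta_switch(u)) >= 0))  # monotone
  expect_error(delta_switch(-0.1), "nonnegative")
})

test_that("coefficient fields follow the tissue/tumor piecewise rules", {
  fx <- phantom_fixture(noise_sd = 0)
  params <- default_scenarios()[[1]]  # D_w = 0.015
  study <- make_baseline_study(fx$grid, fx$spec, params)
  co <- build_coefficients(fx$grid, study, params)
  codes <- label_codes()
  lab <- fx$grid$labels
  tumor <- study$enhancing | study$edema | study$necrotic

  expect_true(all(co$D[lab == codes[["WHITE"]]] == params$D_w))
  expect_true(all(co$D[lab == codes[["GRAY"]] & !tumor] == params$D_w / 2))
  expect_true(all(co$D[tumor] == params$D_w))  # tumor overrides gray
  csf_bg <- lab == codes[["CSF"]] | lab == codes[["BACKGROUND"]]
  expect_true(all(co$D[csf_bg] == 0))
  expect_true(all(co$rho[csf_bg] == 0) && all(co$k[csf_bg] == 0))

  expect_true(all(co$rho[study$enhancing] == log(2) / params$rhohat1))
  expect_true(all(co$k[study$enhancing] == log(2) / params$khat1))
  normal <- !study$enhancing & !csf_bg
  expect_true(all(co$rho[normal] == log(2) / params$rhohat0))
  expect_true(all(co$k[normal] == log(2) / params$khat0))
})

test_that("initial-state imputation maps intensity extremes to window ends", {
  params <- default_scenarios()[[1]]  # I_c = [0.16, 0.80], I_e = [0.012, 0.03]
  fx <- phantom_fixture(noise_sd = 0.02, seed = 8)
  study <- make_baseline_study(fx$grid, fx$spec, params)
  state <- impute_initial_state(study, params)

  i_max_t1c <- which(study$enhancing)[which.max(study$t1c[study$enhancing])]
  expect_equal(state$p[i_max_t1c], 0.80)
  i_min_t1c <- which(study$enhancing)[which.min(study$t1c[study$enhancing])]
  expect_equal(state$p[i_min_t1c], 0.16)
  # density DECREASES with T2 signal in edema
  i_max_t2 <- which(study$edema)[which.max(study$t2[study$edema])]
  expect_equal(state$p[i_max_t2], 0.012)
  expect_identical(state$t, 0)

  # constant-intensity enhancing mask maps to the window midpoint
  study2 <- study
  study2$t1c[study2$enhancing] <- 0.7
  st2 <- impute_initial_state(study2, params)
  expect_true(all(abs(st2$p[study2$enhancing] - (0.16 + 0.80) / 2) < 1e-12))

  # no enhancing tumor: interval excluded upstream, imputation refuses
  study3 <- study
  study3$enhancing[] <- FALSE
  expect_error(impute_initial_state(study3, params), "empty enhancing mask")
})

test_that("diffusion divergence: constants, conservation, hand-computed case", {
  dims <- c(7, 6, 5)
  D <- array(runif(prod(dims), 0.01, 0.06), dim = dims)
  sp <- c(0.9, 0.9, 7)
  # gradient of a constant is zero
  expect_equal(diffusion_divergence(array(2.5, dims), D, sp),
               array(0, dims))
  # discrete conservation: divergence sums to zero with no-flux edges
  f <- array(0, dims); f[4, 3, 3] <- 1
  expect_lt(abs(sum(diffusion_divergence(f, D, sp))), 1e-12)
  fr <- array(runif(prod(dims)), dims)
  expect_lt(abs(sum(diffusion_divergence(fr, D, sp))), 1e-12)

  # 1-D three-voxel line, D = (1, 1, 0), values (0, 1, 0), unit spacing:
  # harmonic-mean face diffusivities are (1, 0), so only the left face
  # carries flux; hand evaluation gives divergence (+1, -1, 0)
  d1 <- array(c(1, 1, 0), dim = c(3, 1, 1))
  v1 <- array(c(0, 1, 0), dim = c(3, 1, 1))
  out <- diffusion_divergence(v1, d1, c(1, 1, 1))
  expect_equal(as.vector(out), c(1, -1, 0))

  expect_error(
    diffusion_divergence(array(0, c(2, 2, 2)), array(0, c(3, 2, 2)), sp),
    "dimension mismatch")
})

test_that("reaction kinetics: exponential at low density, pure transfer at capacity", {
  rho <- 0.03; k <- 0.05
  expect_equal(reaction_rates(0, 0.4, rho, k),
               list(dp_react = 0, dq_react = 0))
  # p + q -> 0: growth ~ rho p, quiescence ~ 0
  r <- reaction_rates(1e-6, 0, rho, k)
  expect_equal(r$dp_react, rho * 1e-6, tolerance = 1e-9)
  expect_lt(r$dq_react, 1e-20)
  # p + q = 1: pure transfer, total conserved
  r1 <- reaction_rates(0.3, 0.7, rho, k)
  expect_equal(r1$dp_react, -k * 0.3)
  expect_equal(r1$dq_react, k * 0.3)
  expect_equal(r1$dp_react + r1$dq_react, 0)
  expect_error(reaction_rates(-0.1, 0, rho, k), "nonnegative")
})

test_that("pure diffusion conserves total cell mass over 60 days", {
  params <- default_scenarios()[[3]]  # largest D_w
  fx <- phantom_fixture(noise_sd = 0)
  study <- make_baseline_study(fx$grid, fx$spec, params)
  state <- impute_initial_state(study, params)
  co <- build_coefficients(fx$grid, study, params)
  co$rho[] <- 0; co$k[] <- 0
  fin <- simulate_growth(state, co, 60)
  vv <- voxel_volume(fx$grid)
  m0 <- sum(state$p + state$q) * vv
  m1 <- sum(fin$p + fin$q) * vv
  expect_lt(abs(m1 - m0) / m0, 1e-8)
})

test_that("uniform fields match the independent well-mixed ODE oracle", {
  grid <- uniform_white_grid()
  study <- uniform_enhancing_study(grid)
  for (i in c(1, 5, 9)) {
    params <- default_scenarios()[[i]]
    co <- build_coefficients(grid, study, params)
    p0 <- 0.3
    st <- make_state(array(p0, grid$dims))
    fin <- simulate_growth(st, co, 60)
    # diffusion vanishes for uniform fields: voxelwise 2-ODE dynamics
    expect_lt(max(fin$p) - min(fin$p), 1e-12)
    ref <- oracle_well_mixed(p0, 0, log(2) / params$rhohat1,
                             log(2) / params$khat1, 60)
    expect_lt(abs(fin$p[1] - ref[["p"]]) / ref[["p"]], 1e-3)
    expect_lt(abs(fin$q[1] - ref[["q"]]) / ref[["q"]], 1e-3)
  }
})

test_that("small densities grow exponentially at the prescribed rate", {
  grid <- uniform_white_grid()
  study <- uniform_enhancing_study(grid)
  params <- default_scenarios()[[1]]
  co <- build_coefficients(grid, study, params)
  st <- make_state(array(1e-4, grid$dims))
  fin <- simulate_growth(st, co, 60)
  rho <- log(2) / params$rhohat1
  expect_lt(abs(fin$p[1] / (1e-4 * exp(60 * rho)) - 1), 0.02)
})

test_that("densities never leak into CSF or background", {
  params <- default_scenarios()[[3]]
  fx <- phantom_fixture(noise_sd = 0)
  study <- make_baseline_study(fx$grid, fx$spec, params)
  state <- impute_initial_state(study, params)
  co <- build_coefficients(fx$grid, study, params)
  fin <- simulate_growth(state, co, 60,
                         solver_options(checkpoint_days = c(20, 40)))
  codes <- label_codes()
  dead <- fx$grid$labels == codes[["CSF"]] |
    fx$grid$labels == codes[["BACKGROUND"]]
  for (cp in c(attr(fin, "checkpoints"), list(fin)))
    expect_true(all(cp$p[dead] == 0) && all(cp$q[dead] == 0))
})

test_that("integration is deterministic and respects checkpoint times", {
  params <- default_scenarios()[[5]]
  fx <- phantom_fixture(noise_sd = 0)
  study <- make_baseline_study(fx$grid, fx$spec, params)
  state <- impute_initial_state(study, params)
  co <- build_coefficients(fx$grid, study, params)
  opts <- solver_options(checkpoint_days = c(10, 30))
  a <- simulate_growth(state, co, 45, opts)
  b <- simulate_growth(state, co, 45, opts)
  expect_identical(a$p, b$p)
  expect_identical(a$q, b$q)
  cps <- attr(a, "checkpoints")
  expect_equal(vapply(cps, function(s) s$t, numeric(1)), c(10, 30, 45))
  expect_error(simulate_growth(state, co, -1), "positive")
})
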