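test_that("frequency-dependent calibration matches the density-dependent equilibrium", {
  p <- preset_params("fig2")
  eq_dd <- run_to_equilibrium(beta_J = p$beta_A, params = p)
  expect_identical(eq_dd$classification, "endemic")
  bfd <- calibrate_fd_beta(p)
  # lambda_FD = beta I / N matches lambda_DD = beta I exactly when
  # beta_FD = beta_DD * N*
  expect_equal(bfd, p$beta_A * total_density(eq_dd$state), tolerance = 1e-9)
  pfd <- calibrated_fd_params(p)
  eq_fd <- run_to_equilibrium(beta_J = pfd$beta_A, params = pfd)
  y_dd <- unclass(eq_dd$state)[1:4]
  y_fd <- unclass(eq_fd$state)[1:4]
  expect_lt(max(abs(y_fd - y_dd) / y_dd), 1e-6)
  expect_equal(eq_fd$prevalence, eq_dd$prevalence, tolerance = 1e-6)
  expect_equal(eq_fd$juvenile_fraction, eq_dd$juvenile_fraction,
               tolerance = 1e-6)
})

test_that("calibration is infeasible without an endemic reference", {
  p <- update_params(preset_params("fig2"), beta_A = 0.0008)  # R0 < 1
  expect_error(calibrate_fd_beta(p), "disease-free")
  expect_error(calibrate_fd_beta(update_params(p, a0 = 0.01)), "not viable")
})

test_that("evolution endpoints hit the documented attractors", {
  # weak trade-off: minimum susceptibility
  p_mn <- fig1(c_strength = 0.05, c_shape = -1.5)
  ev <- evolve_to_endpoint(p_mn)
  expect_equal(ev$beta_star, p_mn$beta_A)
  expect_identical(ev$attractor, "boundary_min")
  # near-certain maturation: shortening the juvenile period buys nothing
  p3 <- preset_params("fig3")
  p_hi <- update_params(p3, g0 = p3$b * 0.97 / 0.03)   # maturation prob 0.97
  ev_hi <- evolve_to_endpoint(p_hi)
  expect_equal(ev_hi$beta_star / p_hi$beta_A, 1, tolerance = 1e-9)
  # CSS preset: interior endpoint at the singular strategy
  p_css <- preset_params("fig1c")
  ev_css <- evolve_to_endpoint(p_css)
  expect_identical(ev_css$attractor, "interior")
  expect_equal(ev_css$beta_star,
               find_singular_strategies(p_css)$strategies$beta_J_star[1],
               tolerance = 1e-6)
})

test_that("sweeps report the stated axis coordinate and reduce at one point", {
  p <- preset_params("fig2")
  sw <- sweep_experiment("lifespan", 8, p)
  r <- sw$records
  expect_equal(r$axis_value, 8)
  expect_equal(r$b, 1 / 8)          # lifespan coordinate is 1/b as run
  expect_equal(r$g0, p$g0)          # g0 fixed on the lifespan axis
  ev <- evolve_to_endpoint(update_params(p, b = 1 / 8))
  expect_equal(r$evolved_beta_ratio, ev$beta_star / p$beta_A,
               tolerance = 1e-9)
  sw2 <- sweep_experiment("maturation_probability", 0.4, p)
  expect_equal(sw2$records$g0 / (p$b + sw2$records$g0), 0.4)
  expect_equal(sw2$records$b, p$b)  # b fixed on the maturation axis
})

test_that("evolving susceptibility upward raises equilibrium prevalence", {
  p <- preset_params("fig2")
  sw <- sweep_experiment("lifespan", c(4, 10, 30), p)
  r <- sw$records
  up <- r$evolved_beta_ratio > 1 & r$evolved_viable
  expect_true(any(up))
  expect_true(all(r$evolved_prevalence[up] >= r$initial_prevalence[up]))
})

test_that("frequency-dependent sweep shares initial structure with its density-dependent reference", {
  p <- preset_params("fig4m")
  vals <- c(4, 8)
  sw_dd <- sweep_experiment("lifespan", vals, p, mode = "density_dependent")
  sw_fd <- sweep_experiment("lifespan", vals, p, mode = "frequency_dependent")
  expect_true(all(sw_fd$records$calibration_ok))
  expect_equal(sw_fd$records$initial_prevalence,
               sw_dd$records$initial_prevalence, tolerance = 1e-6)
  expect_equal(sw_fd$records$initial_juvenile_fraction,
               sw_dd$records$initial_juvenile_fraction, tolerance = 1e-6)
})

test_that("suicide gaps exist only under frequency-dependent transmission", {
  p_dd <- preset_params("fig2")
  expect_warning(gap <- suicide_gap(c(3, 5), p_dd), "density-dependent")
  expect_length(gap, 0)
  # short-lifespan gap for the calibrated maturation preset
  p_fd <- update_params(preset_params("fig4m"),
                        transmission_mode = "frequency_dependent")
  gap_fd <- suicide_gap(c(2.15, 2.3, 3, 6), p_fd)
  expect_gte(length(gap_fd), 1)
  expect_lt(max(unlist(gap_fd)), 3)   # confined to short lifespans
  sw <- attr(gap_fd, "sweep")
  expect_true(all(sw$records$evolved_viable[sw$records$axis_value >= 3]))
})
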