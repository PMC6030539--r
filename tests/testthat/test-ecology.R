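test_that("closed-form disease-free equilibrium matches long-time integration", {
  p <- fig1()
  dfe <- disease_free_equilibrium(p$beta_A, p)
  expect_equal(total_density(dfe), 930)          # (1/q)(1 - b(b+g0)/(a0 g0))
  expect_equal(dfe[["S_J"]], 930 / (1 + p$g0 / p$b), tolerance = 1e-12)
  # oracle: integrate from a small positive disease-free state
  sol <- juvsus:::.integrate(c(1, 1, 0, 0), p$beta_A, p, c(0, 5000),
                             rtol = 1e-11, atol = 1e-12)
  expect_equal(as.numeric(sol[2, 2:5]), unname(unclass(dfe)[1:4]),
               tolerance = 1e-6)
  # sub-replacement demography: all-zero state
  p_bad <- update_params(p, a0 = 0.01)
  expect_equal(total_density(disease_free_equilibrium(p_bad$beta_A, p_bad)), 0)
  # disease parameters cannot affect a disease-free state
  p_alt <- update_params(p, alpha = 2, gamma = 0.01)
  expect_equal(unclass(disease_free_equilibrium(p$beta_A, p_alt)),
               unclass(dfe))
})

test_that("R0 has the next-generation properties", {
  p <- fig1()
  expect_equal(basic_reproduction_number(p$beta_A, p), 1.690909,
               tolerance = 1e-6)
  # no transmission, no pathogen
  p0 <- update_params(p, beta_A = 0)
  expect_equal(basic_reproduction_number(0, p0), 0)
  # DD: linear in the transmission coefficients
  p2 <- update_params(p, beta_A = 2 * p$beta_A)
  expect_equal(basic_reproduction_number(2 * p$beta_A, p2),
               2 * basic_reproduction_number(p$beta_A, p))
  # nonviable host: undefined
  expect_error(basic_reproduction_number(0.002, update_params(p, a0 = 0.01)),
               "not viable")
})

test_that("the R0 = 1 threshold agrees with the integration-based invasion boundary", {
  p <- fig1()
  # closed-form critical scale factor on both transmission coefficients
  r0_of <- function(s) basic_reproduction_number(s * p$beta_A,
                                                 update_params(p, beta_A = s * p$beta_A))
  s_star <- stats::uniroot(function(s) r0_of(s) - 1, c(0.2, 1.5),
                           tol = 1e-10)$root
  # oracle: bisection on the endemic/disease-free transition found by
  # direct equilibration
  classify <- function(s) {
    ps <- update_params(p, beta_A = s * p$beta_A)
    run_to_equilibrium(beta_J = ps$beta_A, params = ps)$classification
  }
  lo <- 0.8 * s_star; hi <- 1.2 * s_star
  expect_identical(classify(lo), "disease_free")
  expect_identical(classify(hi), "endemic")
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (classify(mid) == "endemic") hi <- mid else lo <- mid
  }
  expect_lt(abs((lo + hi) / 2 - s_star), 1e-4 * s_star + (hi - lo))
})

test_that("run_to_equilibrium classifies attractors and respects fixed points", {
  p <- fig1()
  # R0 > 1 from the default init: endemic with positive prevalence
  eq <- run_to_equilibrium(beta_J = p$beta_A, params = p)
  expect_identical(eq$classification, "endemic")
  expect_true(eq$converged)
  expect_gt(eq$prevalence, 0)
  expect_lt(eq$residual, 1e-9)
  # R0 < 1: settles on the disease-free equilibrium to 1e-6
  p_lo <- update_params(p, beta_A = 0.0008)
  eq_lo <- run_to_equilibrium(beta_J = p_lo$beta_A, params = p_lo)
  expect_identical(eq_lo$classification, "disease_free")
  expect_equal(unname(unclass(eq_lo$state)[1:4]),
               unname(unclass(disease_free_equilibrium(p_lo$beta_A, p_lo))[1:4]),
               tolerance = 1e-6)
  # starting at an equilibrium stays there
  eq2 <- run_to_equilibrium(init = eq$state, beta_J = p$beta_A, params = p)
  expect_equal(unname(unclass(eq2$state)[1:4]),
               unname(unclass(eq$state)[1:4]), tolerance = 1e-6)
  # extinct init is absorbing
  eq0 <- run_to_equilibrium(init = population_state(0, 0, 0, 0),
                            beta_J = p$beta_A, params = p)
  expect_identical(eq0$classification, "extinct")
})

test_that("population-structure summaries are exact fractions", {
  s <- population_state(10, 30, 5, 5)
  out <- summarize_structure(s)
  expect_equal(unname(out), c(0.2, 0.3))
  expect_equal(unname(summarize_structure(population_state(3, 7, 0, 0))[1]), 0)
  expect_equal(unname(summarize_structure(population_state(4, 0, 6, 0))[2]), 1)
  expect_error(summarize_structure(population_state(0, 0, 0, 0)), "empty")
})

test_that("initial prevalence increases with lifespan over the sweep grid", {
  p <- preset_params("fig2")
  prev <- vapply(c(3, 5, 10, 25, 60), function(L) {
    run_to_equilibrium(beta_J = p$beta_A,
                       params = update_params(p, b = 1 / L))$prevalence
  }, numeric(1))
  expect_true(all(diff(prev) > 0))
})

test_that("density-dependent endemic equilibria never lose the host", {
  p <- preset_params("fig2")
  for (L in c(2, 5, 20, 80)) for (ratio in c(1, 2, 3)) {
    eq <- run_to_equilibrium(beta_J = ratio * p$beta_A,
                             params = update_params(p, b = 1 / L))
    expect_true(eq$classification %in% c("endemic", "disease_free"))
    expect_gt(total_density(eq$state), 0)
  }
})

test_that("equilibrium reports serialize to JSON and data frames", {
  p <- fig1()
  eq <- run_to_equilibrium(beta_J = p$beta_A, params = p)
  js <- jsonlite::fromJSON(equilibrium_to_json(eq))
  expect_equal(js$classification, "endemic")
  expect_equal(js$state$S_J, unname(unclass(eq$state)[1]), tolerance = 1e-12)
  df <- as.data.frame(eq)
  expect_equal(df$prevalence, eq$prevalence)
})
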