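test_that("resident neutrality holds for both fitness methods", {
  set.seed(21)
  for (i in 1:12) {
    p <- draw_admissible()
    x <- stats::runif(1, p$beta_A, p$d * p$beta_A)
    st <- resident_state(x, p)
    if (is.null(st)) next
    expect_lt(abs(invasion_fitness(x, x, p, "analytic", resident = st)), 1e-10)
    expect_lt(abs(invasion_fitness(x, x, p, "eigenvalue", resident = st)), 1e-8)
  }
})

test_that("analytic and eigenvalue fitness agree in sign on random draws", {
  set.seed(22)
  n <- 0
  while (n < 100) {
    p <- draw_admissible()
    br <- stats::runif(1, p$beta_A, p$d * p$beta_A)
    st <- resident_state(br, p)
    if (is.null(st)) next
    n <- n + 1
    bm <- stats::runif(1, p$beta_A, p$d * p$beta_A)
    wa <- invasion_fitness(bm, br, p, "analytic", resident = st)
    we <- invasion_fitness(bm, br, p, "eigenvalue", resident = st)
    if (abs(wa) > 1e-8 && abs(we) > 1e-10)
      expect_identical(sign(wa), sign(we))
  }
})

test_that("the closed-form gradient equals the mutant finite difference of fitness", {
  set.seed(23)
  checked <- 0
  while (checked < 10) {
    p <- draw_admissible()
    br <- stats::runif(1, 1.05 * p$beta_A, 0.95 * p$d * p$beta_A)
    st <- resident_state(br, p)
    if (is.null(st)) next
    g <- selection_gradient(br, p, resident = st)
    h <- 1e-5 * (p$d - 1) * p$beta_A
    w <- invasion_fitness(br + c(-h, h), br, p, resident = st)
    fd <- (w[2] - w[1]) / (2 * h)
    if (abs(fd) < 1e-12) next
    expect_lt(abs(g - fd) / abs(fd), 1e-4)
    checked <- checked + 1
  }
})

test_that("fitness in a disease-free resident reduces to the demographic invasion condition", {
  p <- fig1(beta_A = 0.0008, c_strength = 0.5, c_shape = -2)  # R0 < 1
  eq <- run_to_equilibrium(beta_J = p$beta_A, params = p)
  expect_identical(eq$classification, "disease_free")
  # with no disease the benefit has no cost: gradient is positive throughout
  g <- vapply(c(1, 1.5, 2.5) * p$beta_A,
              function(b) selection_gradient(b, p, resident = eq), numeric(1))
  expect_true(all(g > 0))
})

test_that("an extinct resident admits no invasion analysis", {
  p <- fig1(a0 = 0.01)
  expect_error(invasion_fitness(p$beta_A, p$beta_A, p), "extinct")
  expect_error(selection_gradient(p$beta_A, p), "extinct")
})

test_that("with no benefit the gradient never favours susceptibility", {
  set.seed(24)
  for (i in 1:4) {
    p <- update_params(draw_admissible(), c_strength = 0)
    for (beta in c(1.01, 1.5, 2.2) * p$beta_A) {
      st <- resident_state(beta, p)
      if (is.null(st)) next
      expect_lte(selection_gradient(beta, p, resident = st), 1e-12)
    }
  }
})

test_that("singular strategies are located and classified across known cells", {
  # CSS cell: one interior strategy, both ES and CS
  ss_css <- find_singular_strategies(preset_params("fig1c"))
  expect_equal(nrow(ss_css$strategies), 1)
  expect_identical(ss_css$strategies$label, "CSS")
  expect_equal(ss_css$strategies$beta_J_star / 0.002, 1.75, tolerance = 0.01)
  # gradient at the root is numerically zero
  expect_lt(abs(selection_gradient(ss_css$strategies$beta_J_star,
                                   preset_params("fig1c"))), 1e-8)
  # repeller cell
  ss_re <- find_singular_strategies(preset_params("fig1d"))
  expect_true("repeller" %in% ss_re$strategies$label)
  # weak trade-off: no interior root, minimum-susceptibility endpoint
  p_mn <- fig1(c_strength = 0.05, c_shape = -1.5)
  ss_mn <- find_singular_strategies(p_mn)
  expect_equal(nrow(ss_mn$strategies), 0)
  expect_true(ss_mn$endpoints["min_attracting"])
  expect_false(ss_mn$endpoints["max_attracting"])
})

test_that("outcome classification follows the singular-strategy pattern", {
  expect_identical(classify_tradeoff_point(fig1(c_strength = 0.05,
                                                c_shape = -1.5)), "MN")
  expect_identical(classify_tradeoff_point(fig1(c_strength = 4,
                                                c_shape = -1.5)), "MX")
  expect_identical(classify_tradeoff_point(preset_params("fig1c")), "CSS")
  expect_identical(classify_tradeoff_point(preset_params("fig1d")), "RE")
  expect_identical(classify_tradeoff_point(preset_params("fig1e")), "RE_BR")
})

test_that("classification is invariant to trait-grid refinement", {
  for (name in c("fig1c", "fig1d")) {
    p <- preset_params(name)
    expect_identical(classify_tradeoff_point(p, grid_n = 101),
                     classify_tradeoff_point(p, grid_n = 202))
  }
})

test_that("trade-off space map runs MN to CSS to MX with increasing strength", {
  p <- fig1(c_shape = -1.5)
  m <- tradeoff_space_map(p, strength_grid = c(0.05, 0.4, 4),
                          shape_grid = -1.5, grid_n = 101)
  expect_identical(as.vector(m$labels), c("MN", "CSS", "MX"))
  # 1 x 1 grid reduces to classify_tradeoff_point
  m1 <- tradeoff_space_map(p, 0.4, -1.5, grid_n = 101)
  expect_identical(as.vector(m1$labels), "CSS")
})

test_that("pairwise invasibility has a neutral diagonal matching the gradient sign", {
  p <- preset_params("fig1c")
  pip <- pairwise_invasibility(p, grid_n = 41)
  expect_true(all(diag(pip$sign) == 0))
  # first off-diagonal reproduces the gradient's sign
  prof <- find_singular_strategies(p, grid_n = 41)$profile
  for (i in c(5, 15, 25, 35)) {
    g <- prof$gradient[i]
    expect_identical(sign(pip$fitness[i, i + 1]), sign(g))
    expect_identical(sign(pip$fitness[i, i - 1]), -sign(g))
  }
  # at the CSS the mutant column changes sign from + to - across the root
  star <- find_singular_strategies(p)$strategies$beta_J_star[1]
  k <- findInterval(star, pip$beta)
  expect_gt(pip$fitness[k - 3, k - 2], 0)   # below the CSS, upward mutants invade
  expect_lt(pip$fitness[k + 3, k + 4], 0)   # above it, they do not
})
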