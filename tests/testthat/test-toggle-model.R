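# analytic critical synthesis rate of the symmetric toggle, used as the
# independent oracle: the symmetric fixed point s solves alpha = s(1+s^beta)
# and destabilises when beta*s^beta/(1+s^beta) > 1, i.e. s^beta(beta-1) > 1,
# giving s_c = (beta-1)^(-1/beta) and alpha_c = s_c * beta/(beta-1).
alpha_c_analytic <- function(beta) {
  if (beta <= 1) return(NA_real_)
  sc <- (beta - 1)^(-1 / beta)
  sc * beta / (beta - 1)
}

test_that("rate equations evaluate exactly", {
  m <- toggle_model(alpha1 = 2, alpha2 = 2, beta1 = 2, beta2 = 2)
  expect_equal(toggle_rates(c(0, 0), m), c(2, 2))
  m0 <- toggle_model(alpha1 = 3, alpha2 = 5, beta1 = 0, beta2 = 0)
  expect_equal(toggle_rates(c(1, 2), m0), c(3 / 2 - 1, 5 / 2 - 2))
  m3 <- toggle_model(3, 3, 2, 2)
  expect_equal(toggle_rates(c(1, 1), m3), c(0.5, 0.5))
  expect_error(toggle_model(alpha1 = 0), "alpha")
  expect_error(toggle_model(beta1 = -1), "beta")
})

test_that("fixed points of the bistable reference case are exact", {
  m <- toggle_model(3, 3, 2, 2)
  fp <- fixed_points(m)
  expect_equal(nrow(fp), 3L)
  expect_equal(sum(fp$class == "stable_node"), 2L)
  expect_equal(sum(fp$class == "saddle"), 1L)
  # symmetric saddle at s solving s + s^3 = 3 (independent root oracle)
  s <- stats::uniroot(function(x) x + x^3 - 3, c(1, 1.5), tol = 1e-12)$root
  saddle <- fp[fp$class == "saddle", ]
  expect_equal(saddle$x, s, tolerance = 1e-6)
  expect_equal(saddle$y, s, tolerance = 1e-6)
  # stable nodes mirror each other and sit near (2.62, 0.38)
  nodes <- fp[fp$class == "stable_node", ]
  expect_equal(sort(nodes$x), sort(nodes$y), tolerance = 1e-8)
  expect_equal(max(nodes$x), 2.62, tolerance = 1e-2)
  expect_equal(min(nodes$y), 0.38, tolerance = 1e-2)
  # every fixed point satisfies both rate equations
  for (i in seq_len(nrow(fp)))
    expect_lt(sqrt(sum(toggle_rates(c(fp$x[i], fp$y[i]), m)^2)), 1e-9)
  expect_true(is_bistable(m))
})

test_that("eigenvalue classification agrees with det/trace", {
  for (pars in list(c(3, 3, 2, 2), c(0.5, 0.5, 2, 2), c(3, 3, 1, 1),
                    c(2, 4, 3, 2))) {
    m <- toggle_model(pars[1], pars[2], pars[3], pars[4])
    fp <- fixed_points(m)
    for (i in seq_len(nrow(fp))) {
      # independent 2x2 oracle from determinant and trace
      h <- 1e-7; x <- fp$x[i]; y <- fp$y[i]
      J <- cbind((toggle_rates(c(x + h, y), m) - toggle_rates(c(x - h, y), m)) / (2 * h),
                 (toggle_rates(c(x, y + h), m) - toggle_rates(c(x, y - h), m)) / (2 * h))
      det_ <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
      tr_ <- J[1, 1] + J[2, 2]
      cls <- if (det_ < 0) "saddle" else if (tr_ < 0) "stable_node" else "other"
      expect_equal(fp$class[i], cls)
    }
  }
})

test_that("the monostable cases have the closed-form equilibria", {
  # beta = 1: x = y solves x(1 + x) = 3 -> (-1 + sqrt(13)) / 2
  fp <- fixed_points(toggle_model(3, 3, 1, 1))
  expect_equal(nrow(fp), 1L)
  expect_equal(fp$x, (-1 + sqrt(13)) / 2, tolerance = 1e-9)
  expect_equal(fp$class, "stable_node")
  # low synthesis rate below threshold: single stable point
  fp2 <- fixed_points(toggle_model(0.5, 0.5, 2, 2))
  expect_equal(nrow(fp2), 1L)
  expect_equal(fp2$class, "stable_node")
  expect_false(is_bistable(toggle_model(0.5, 0.5, 2, 2)))
})

test_that("bifurcation scan agrees with the analytic critical rate", {
  expect_equal(bifurcation_scan(2), alpha_c_analytic(2), tolerance = 1e-3)
  expect_equal(bifurcation_scan(3), alpha_c_analytic(3), tolerance = 1e-3)
  expect_equal(alpha_c_analytic(3), 1.1906, tolerance = 1e-4)
  # beta = 1: monostable over the whole grid
  expect_true(is.na(bifurcation_scan(1)))
})

test_that("fixed-point counts match the analytic criterion on a grid", {
  for (beta in c(1.5, 2, 3, 4)) {
    ac <- alpha_c_analytic(beta)
    for (alpha in c(0.2, 0.6 * ac, 0.95 * ac, 1.05 * ac, 3 * ac, 5)) {
      m <- toggle_model(alpha, alpha, beta, beta)
      expected <- if (alpha > ac) 3L else 1L
      if (abs(alpha - ac) / ac > 0.02)  # skip degenerate neighbourhood
        expect_equal(nrow(fixed_points(m)), expected)
    }
  }
})

test_that("trajectories stay put at equilibria and converge to the right node", {
  m <- toggle_model(3, 3, 2, 2)
  nodes <- fixed_points(m)
  hi <- nodes[which.max(nodes$x), ]
  tr <- toggle_trajectory(m, c(hi$x, hi$y), t_end = 10)
  expect_lt(max(abs(tr$x - hi$x)), 1e-6)
  expect_lt(max(abs(tr$y - hi$y)), 1e-6)
  tr2 <- toggle_trajectory(m, c(3, 0.1), t_end = 100)
  expect_true(attr(tr2, "converged"))
  expect_equal(attr(tr2, "final")[1], hi$x, tolerance = 1e-6)
  expect_equal(attr(tr2, "final")[2], hi$y, tolerance = 1e-6)
  expect_true(all(tr2$x >= 0 & tr2$y >= 0))
  expect_warning(toggle_trajectory(m, c(3, 0.1), t_end = 0.5), "converge")
  expect_error(toggle_trajectory(m, c(-1, 0)), "non-negative")
})

test_that("basin map is symmetric under coordinate swap", {
  m <- toggle_model(3, 3, 2, 2)
  grid <- seq(0.2, 2.8, length.out = 7)
  pm <- phase_map(m, grid, grid, t_end = 300)
  nodes <- attr(pm, "nodes")
  expect_equal(nrow(nodes), 2L)
  # map node index to its mirror under (x,y) -> (y,x)
  mirror <- vapply(seq_len(2), function(i)
    which.min((nodes$x - nodes$y[i])^2 + (nodes$y - nodes$x[i])^2),
    integer(1))
  for (i in seq_len(nrow(pm))) {
    j <- which(pm$x0 == pm$y0[i] & pm$y0 == pm$x0[i])
    if (!is.na(pm$basin[i]) && !is.na(pm$basin[j]))
      expect_equal(pm$basin[j], mirror[pm$basin[i]])
  }
})

test_that("stochastic simulation is reproducible and degenerates correctly", {
  m <- toggle_model(3, 3, 2, 2)
  e1 <- stochastic_simulate(m, noise_sd = 0.05, n_steps = 200, dt = 0.05,
                            seed = 3, n_paths = 4)
  e2 <- stochastic_simulate(m, noise_sd = 0.05, n_steps = 200, dt = 0.05,
                            seed = 3, n_paths = 4)
  expect_identical(e1$x, e2$x)
  expect_true(all(e1$x >= 0 & e1$y >= 0))
  expect_error(stochastic_simulate(m, 0.05, 10, dt = 0.5), "too large")
  # zero noise follows the deterministic flow
  e0 <- stochastic_simulate(m, noise_sd = 0, n_steps = 1000, dt = 0.01,
                            init = c(3, 0.1))
  tr <- suppressWarnings(toggle_trajectory(m, c(3, 0.1), t_end = 10,
                                           dt_out = 0.01))
  expect_equal(e0$x[1001, 1], tr$x[1001], tolerance = 1e-2)
  expect_equal(e0$y[1001, 1], tr$y[1001], tolerance = 1e-2)
  # the simulate() generic wraps the same machinery
  s <- simulate(m, nsim = 2, seed = 3, noise_sd = 0.05, n_steps = 200,
                dt = 0.05)
  expect_identical(dim(s$x), c(201L, 2L))
})

test_that("fluctuations grow as the bifurcation is approached", {
  m_far <- toggle_model(0.8, 0.8, 2, 2)
  m_near <- toggle_model(1.05, 1.05, 2, 2)
  wins <- vapply(1:5, function(i) {
    vf <- stationary_variance(stochastic_simulate(
      m_far, 0.05, n_steps = 2000, dt = 0.05, seed = i, n_paths = 10))["var_x"]
    vn <- stationary_variance(stochastic_simulate(
      m_near, 0.05, n_steps = 2000, dt = 0.05, seed = 100 + i,
      n_paths = 10))["var_x"]
    vn > vf
  }, logical(1))
  expect_gte(mean(wins), 0.6)
})
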