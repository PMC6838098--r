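logistic_exact <- function(g, u0, t) {
  g * u0 * exp(g * t) / (g + u0 * (exp(g * t) - 1))
}

test_that("initial colony indicator covers exactly the requested nodes", {
  m <- unit_square_mesh(0.2)
  full <- initial_condition(m, c(0.5, 0.5), 2, amplitude = 4)
  expect_equal(full, rep(4, nrow(m$nodes)))
  small <- initial_condition(m, c(0, 0), 0.05, amplitude = 10)
  expect_equal(which(small > 0),
               which(sqrt(rowSums(m$nodes^2)) <= 0.05))
  expect_error(initial_condition(m, c(0.07, 0.07), 0.01),
               "configuration error")
  expect_error(initial_condition(m, c(0.5, 0.5), -1), "positive")
})

test_that("zero is a fixed point and uniform states follow the scalar update", {
  m <- unit_square_mesh(0.25)
  n <- nrow(m$nodes)
  co <- coefficient_set(nu = 3e-4, gamma = 6)
  sys <- assemble_system(m, co)
  z <- imex_step(sys, rep(0, n), 1 / 120,
                 function(u) reaction_load(m, u, 6))
  expect_equal(z, rep(0, n), tolerance = 1e-14)

  u0 <- 0.4; g <- 6; dt <- 1 / 120
  u1 <- imex_step(sys, rep(u0, n), dt, function(u) reaction_load(m, u, g))
  expect_equal(u1, rep(u0 + dt * u0 * (g - u0), n), tolerance = 1e-10)
})

test_that("one IMEX step is O(dt)-consistent", {
  m <- unit_square_mesh(0.25)
  co <- coefficient_set(nu = 3e-4, gamma = 6)
  sys <- assemble_system(m, co)
  u0 <- initial_condition(m, c(0.5, 0.5), 0.3, 2)
  delta <- vapply(c(1e-3, 5e-4, 2.5e-4), function(dt) {
    u1 <- imex_step(sys, u0, dt, function(u) reaction_load(m, u, 6))
    max(abs(u1 - u0))
  }, 0)
  expect_lt(delta[2], delta[1] * 0.6)
  expect_lt(delta[3], delta[2] * 0.6)
})

test_that("conjugate gradients agrees with the direct solver", {
  m <- unit_square_mesh(0.2)
  co <- coefficient_set(nu = 3e-4, gamma = 6)
  sys <- assemble_system(m, co)
  u0 <- initial_condition(m, c(0.5, 0.5), 0.3, 2)
  ud <- imex_step(sys, u0, 1 / 120, function(u) reaction_load(m, u, 6),
                  solver = "direct")
  uc <- imex_step(sys, u0, 1 / 120, function(u) reaction_load(m, u, 6),
                  solver = "cg")
  expect_equal(uc, ud, tolerance = 1e-8)
  expect_error(invadefem:::pcg_solve(sys$M, rep(1, nrow(m$nodes)),
                                     Matrix::diag(sys$M), tol = 1e-16,
                                     maxit = 2L),
               "numerical error.*residual")
})

test_that("the uniform-field solution converges to the logistic curve in dt", {
  m <- unit_square_mesh(0.25)
  n <- nrow(m$nodes)
  co <- coefficient_set(nu = 5e-4, gamma = 10)
  errs <- vapply(c(1 / 300, 1 / 600, 1 / 1200), function(dt) {
    res <- run_simulation(m, co, rep(0.1, n), dt = dt, T_end = 0.5,
                          probes = list(c(0.5, 0.5)), stride = 1000)
    ex <- logistic_exact(10, 0.1, res$probe_times)
    max(abs(res$probe_series[, 1] - ex) / ex)
  }, 0)
  expect_lt(errs[3], 0.01)
  expect_lt(errs[2], errs[1])
  expect_lt(errs[3], errs[2])
  # first-order scheme: halving dt roughly halves the error
  expect_equal(errs[2] / errs[3], 2, tolerance = 0.2)
})

test_that("a uniform state at carrying capacity is stationary", {
  m <- unit_square_mesh(0.25)
  n <- nrow(m$nodes)
  co <- coefficient_set(nu = 5e-4, gamma = 10)
  res <- run_simulation(m, co, rep(10, n), dt = 1 / 120,
                        T_end = 100 / 120, stride = 100)
  expect_equal(res$snapshots[, ncol(res$snapshots)], rep(10, n),
               tolerance = 1e-8)
})

test_that("hostile terrain (gamma < 0) strictly damps the population", {
  m <- unit_square_mesh(0.25)
  n <- nrow(m$nodes)
  co <- coefficient_set(nu = 5e-4, gamma = -4)
  u0 <- initial_condition(m, c(0.5, 0.5), 0.4, 8)
  res <- run_simulation(m, co, u0, dt = 1 / 120, T_end = 0.5, stride = 5)
  maxu <- apply(res$snapshots, 2, max)
  expect_true(all(diff(maxu) < 0))
  expect_true(all(res$arrival_time[u0 < 1] == Inf))
})

test_that("arrival times are zero where the colony starts above threshold", {
  m <- unit_square_mesh(0.25)
  u0 <- initial_condition(m, c(0, 0), 0.35, 10)
  co <- coefficient_set(nu = 5e-4, gamma = 10)
  res <- run_simulation(m, co, u0, dt = 1 / 120, T_end = 0.1, stride = 100)
  expect_true(all(res$arrival_time[u0 >= 1] == 0))
  expect_true(all(res$arrival_time[u0 < 1] > 0))
  expect_identical(res$snapshots[, 1], u0)
  expect_equal(diff(res$times), rep(res$times[2] - res$times[1],
                                    length(res$times) - 1))
})

test_that("identical inputs give bit-identical trajectories", {
  m <- unit_square_mesh(0.3)
  co <- coefficient_set(nu = 5e-4, gamma = 10)
  u0 <- initial_condition(m, c(0.2, 0.2), 0.3, 10)
  r1 <- run_simulation(m, co, u0, dt = 1 / 120, T_end = 0.3,
                       probes = list(p = c(0.5, 0.5)))
  r2 <- run_simulation(m, co, u0, dt = 1 / 120, T_end = 0.3,
                       probes = list(p = c(0.5, 0.5)))
  expect_identical(r1$snapshots, r2$snapshots)
  expect_identical(r1$probe_series, r2$probe_series)
})

test_that("under-resolved consistent-mass fronts trigger the blow-up guard", {
  m <- generate_mesh(c(0, 1, 0, 0.2), 0.07)
  co <- coefficient_set(nu = 5e-4, gamma = 10)
  u0 <- ifelse(m$nodes[, 1] <= 0.1, 10, 0)
  expect_error(run_simulation(m, co, u0, dt = 1 / 120, T_end = 3,
                              mass = "consistent"),
               "blow-up")
  # the lumped variant stays positive on the same mesh
  res <- run_simulation(m, co, u0, dt = 1 / 120, T_end = 3, mass = "lumped")
  expect_gte(min(res$snapshots), 0)
})

test_that("probe interpolation reproduces nodal values at node locations", {
  m <- unit_square_mesh(0.25)
  co <- coefficient_set(nu = 5e-4, gamma = 10)
  u0 <- initial_condition(m, c(0.3, 0.3), 0.3, 5)
  node <- 7
  res <- run_simulation(m, co, u0, dt = 1 / 120, T_end = 0.05, stride = 1,
                        probes = list(at_node = m$nodes[node, ]))
  expect_equal(res$probe_series[1, "at_node"], unname(u0[node]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$probe_series[nrow(res$probe_series), "at_node"],
               res$snapshots[node, ncol(res$snapshots)],
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(run_simulation(m, co, u0, dt = 1 / 120, T_end = 0.05,
                              probes = list(c(5, 5))), "outside")
})

test_that("front speed recovers an exact affine arrival field", {
  m <- unit_square_mesh(0.2)
  res <- structure(list(arrival_time = 2 + 5 * m$nodes[, 1]),
                   class = "simulation_result")
  fs <- front_speed(res, m, from = c(0.1, 0.5), to = c(0.9, 0.5))
  expect_equal(fs$speed, 1 / 5, tolerance = 1e-10)
  res_inf <- structure(list(arrival_time = rep(Inf, nrow(m$nodes))),
                       class = "simulation_result")
  expect_error(front_speed(res_inf, m, c(0.1, 0.5), c(0.9, 0.5)),
               "data error")
})
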