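test_that("raw moments follow closed forms and flag degeneracy", {
  expect_equal(raw_moments(rep(3, 10), 0), 1)
  expect_error(raw_moments(rep(3, 10), 2), "degeneracy error")
  expect_equal(raw_moments(c(-1, 1), 2), c(1, 0, 1))
  set.seed(1)
  x <- runif(1e5, 0, 2)
  mu <- raw_moments(x, 2)
  se1 <- sqrt(1 / 3 / 1e5)            # sd of U(0,2) mean
  expect_lt(abs(mu[2] - 1), 3 * se1)
  expect_lt(abs(mu[3] - 4 / 3), 3 * sqrt((16 / 5 - 16 / 9) / 1e5))
})

test_that("histogram and sample moments agree on finely binned data", {
  set.seed(2)
  x <- rnorm(2e4, 1, 0.2)
  h <- graphics::hist(x, breaks = 200, plot = FALSE)
  inp_s <- random_input("x", samples = x)
  inp_h <- random_input("x", histogram = list(breaks = h$breaks,
                                              counts = h$counts))
  expect_equal(input_moments(inp_h, 4), input_moments(inp_s, 4),
               tolerance = 1e-3)
})

test_that("a 1-point rule sits at the sample mean with weight 1", {
  set.seed(3)
  inp <- random_input("x", samples = rlnorm(500))
  q <- quadrature_from_moments(inp, 1)
  expect_equal(q$nodes, mean(inp$samples), tolerance = 1e-12)
  expect_equal(q$weights, 1)
})

test_that("exact-moment rules reproduce Gauss-Legendre and Gauss-Hermite", {
  u02 <- random_input("alpha", moments = uniform02_moments(4))
  q <- quadrature_from_moments(u02, 2)
  expect_equal(q$nodes, c(1 - 1 / sqrt(3), 1 + 1 / sqrt(3)),
               tolerance = 1e-10)
  expect_equal(q$weights, c(0.5, 0.5), tolerance = 1e-10)

  nu <- random_input("nu", moments = normal_moments(5e-4, 1.2e-4, 4))
  qn <- quadrature_from_moments(nu, 2)
  expect_equal(qn$nodes, c(3.8e-4, 6.2e-4), tolerance = 1e-10)
  expect_equal(qn$weights, c(0.5, 0.5), tolerance = 1e-10)
})

test_that("moment-built rules integrate monomials up to degree 2m - 1", {
  set.seed(4)
  pools <- list(stats::runif(5e3, 0, 2), stats::rgamma(5e3, 2, 1),
                stats::rnorm(5e3, -1, 0.5))
  for (x in pools) {
    inp <- random_input("x", samples = x)
    for (m in 1:4) {
      q <- quadrature_from_moments(inp, m)
      mu <- input_moments(inp, 2 * m - 1)
      for (k in 0:(2 * m - 1)) {
        got <- sum(q$weights * q$nodes^k)
        expect_equal(got, mu[k + 1], tolerance = 1e-8 * max(1, abs(mu[k + 1])))
      }
      expect_equal(sum(q$weights), 1, tolerance = 1e-12)
      expect_true(min(q$nodes) >= min(x) - 1e-9)
      expect_true(max(q$nodes) <= max(x) + 1e-9)
    }
  }
})

test_that("level-1 Smolyak grids have 2d + 1 points matching the closed form", {
  # (d = 1 is the degenerate case where the combination formula collapses to
  # the plain 2-point rule; covered by the dedicated test below)
  for (d in 2:5) {
    inputs <- lapply(seq_len(d), function(k)
      random_input(paste0("x", k),
                   moments = normal_moments(k, 0.3 * k, 4)))
    g <- smolyak_grid(inputs, level = 1)
    expect_equal(nrow(g$points), 2 * d + 1)
    expect_equal(sum(g$weights), 1, tolerance = 1e-12)
    expect_equal(anyDuplicated(apply(round(g$points, 9), 1, paste,
                                     collapse = "|")), 0L)
    # independent closed form: mean point with weight 1 - d (from the
    # (1,...,1) term minus nothing) plus per-axis 2-point rules at weight 1/2
    means <- vapply(seq_len(d), function(k) k, 0)
    mean_row <- which(apply(g$points, 1, function(p) all(abs(p - means) < 1e-9)))
    expect_length(mean_row, 1)
    expect_equal(g$weights[mean_row], 1 - d, tolerance = 1e-10)
    expect_equal(sort(g$weights[-mean_row]), rep(0.5, 2 * d),
                 tolerance = 1e-10)
  }
})

test_that("1-D level-1 Smolyak collapses to the plain 2-point Gauss rule", {
  inp <- random_input("alpha", moments = uniform02_moments(4))
  g <- smolyak_grid(list(inp), level = 1)
  q <- quadrature_from_moments(inp, 2)
  expect_equal(sort(as.numeric(g$points)), q$nodes, tolerance = 1e-12)
  expect_equal(g$weights[order(as.numeric(g$points))], q$weights,
               tolerance = 1e-12)
})

test_that("the reference two-input grid has the published 5-point structure", {
  inputs <- list(nu = random_input("nu",
                                   moments = normal_moments(5e-4, 1.2e-4, 4)),
                 alpha = random_input("alpha",
                                      moments = uniform02_moments(4)))
  g <- smolyak_grid(inputs, level = 1)
  expect_equal(nrow(g$points), 5)
  expect_equal(sort(g$weights), c(-1, 0.5, 0.5, 0.5, 0.5), tolerance = 1e-10)
})

test_that("projection is exact for constants and degree-1 models", {
  inputs <- list(random_input("a", moments = normal_moments(2, 0.5, 6)),
                 random_input("b", moments = uniform02_moments(6)))
  g <- smolyak_grid(inputs, level = 1)
  basis <- pce_basis(inputs, level = 1)

  const <- pce_project(rep(4.2, nrow(g$points)), g, basis)
  expect_equal(pce_mean(const), 4.2, tolerance = 1e-12)
  expect_equal(max(abs(const$coefficients[-1, ])), 0, tolerance = 1e-12)

  w <- function(X) 1.5 - 2 * X[, 1] + 0.7 * X[, 2]
  expn <- pce_project(w(g$points), g, basis)
  set.seed(6)
  X <- cbind(rnorm(100, 2, 0.5), runif(100, 0, 2))
  expect_equal(as.numeric(pce_eval(expn, X)), w(X), tolerance = 1e-8)
  expect_equal(pce_mean(expn), 1.5 - 2 * 2 + 0.7 * 1, tolerance = 1e-8)
  expect_error(pce_project(rep(1, 3), g, basis), "dimension error")
})

test_that("surrogate Monte Carlo recovers known output spread", {
  inp <- random_input("a", samples = with_seed(7, runif(2e5, 0, 2)))
  g <- smolyak_grid(list(inp), level = 1)
  basis <- pce_basis(list(inp), level = 1)
  expn <- pce_project(as.numeric(g$points), g, basis) # w(x) = x
  mc <- surrogate_mc(expn, list(inp), n_samples = 1e5, seed = 8)
  expect_lt(abs(mc$sd - 1 / sqrt(3)) / (1 / sqrt(3)), 0.02)
  mc2 <- surrogate_mc(expn, list(inp), n_samples = 1e5, seed = 8)
  expect_identical(mc$samples, mc2$samples)
  expect_error(surrogate_mc(expn, list(inp), n_samples = 10), "1000")
})

test_that("zero-variance inputs produce zero spread and a single atom", {
  fixed <- random_input("a", samples = rep(1.3, 500))
  q <- quadrature_from_moments(fixed, 2)
  expect_equal(unique(q$nodes), 1.3)
  other <- random_input("b", moments = uniform02_moments(6))
  g <- smolyak_grid(list(fixed, other), level = 1)
  basis <- pce_basis(list(fixed, other), level = 1)
  w <- 2 + 3 * g$points[, 2]              # depends only on the live input
  expn <- pce_project(w, g, basis)
  expect_equal(pce_mean(expn), 5, tolerance = 1e-10)
  sd_from_coef <- pce_sd(expn)
  expect_equal(sd_from_coef, 3 * sqrt(1 / 3), tolerance = 1e-10)
})

test_that("level-1 chaos mean matches direct Monte Carlo on the logistic model", {
  # uniform-field reduction of the dispersal model: the density follows the
  # scalar IMEX recurrence; treat u(T) as the model output
  imex_logistic <- function(gam, dt = 1 / 120, nstep = 24, u0 = 0.1) {
    u <- rep(u0, length(gam))
    for (k in seq_len(nstep)) u <- u + dt * u * (gam - u)
    u
  }
  set.seed(9)
  inputs <- list(
    nu = random_input("nu", samples = rnorm(2e4, 5e-4, 1.2e-4)),
    alpha = random_input("alpha", samples = runif(2e4, 0.8, 1.2)))
  g <- smolyak_grid(inputs, level = 1)
  basis <- pce_basis(inputs, level = 1)
  evals <- imex_logistic(10 * g$points[, "alpha"])
  expn <- pce_project(evals, g, basis)
  n_direct <- 2e4
  draws <- with_seed(10, sample(inputs$alpha$samples, n_direct, TRUE))
  direct <- imex_logistic(10 * draws)
  se <- stats::sd(direct) / sqrt(n_direct)
  expect_lt(abs(pce_mean(expn) - mean(direct)), 3 * se + 1e-4)
})

test_that("synthetic histogram generation is seeded and validated", {
  inputs <- synth_histograms(reference_uq_inputs(), n = 1e4, seed = 1)
  expect_named(inputs, c("nu", "alpha"))
  se <- 1.2e-4 / sqrt(1e4)
  expect_lt(abs(mean(inputs$nu$samples) - 5e-4), 3 * se)
  expect_true(all(inputs$alpha$samples >= 0 & inputs$alpha$samples <= 2))
  again <- synth_histograms(reference_uq_inputs(), n = 1e4, seed = 1)
  expect_identical(inputs$nu$samples, again$nu$samples)
  expect_error(synth_histograms(list(x = list(family = "beta")), n = 1e3),
               "configuration error")
  expect_error(synth_histograms(reference_uq_inputs(), n = 10), "100")
})
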