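# Shared fixtures, all generated in code.

with_seed <- function(seed, code) invadefem:::with_preserved_seed(seed, code)

unit_right_triangle <- function() {
  tri_mesh(rbind(c(0, 0), c(1, 0), c(0, 1)), rbind(c(1, 2, 3)))
}

unit_square_mesh <- function(h = 0.5) {
  generate_mesh(c(0, 1, 0, 1), h)
}

# small non-trivial mesh (<= 10 triangles) with irregular node positions
small_irregular_mesh <- function() {
  nodes <- rbind(c(0, 0), c(1.1, -0.1), c(2, 0.3), c(0.2, 0.9),
                 c(1.2, 1.0), c(2.1, 1.2), c(0.5, 1.9), c(1.6, 2.0))
  tris <- rbind(c(1, 2, 4), c(2, 5, 4), c(2, 3, 5), c(3, 6, 5),
                c(4, 5, 7), c(5, 8, 7), c(5, 6, 8))
  tri_mesh(nodes, tris)
}

flat_grid <- function(value = 0, n = 11, origin = c(0, 0), cell = 360) {
  elevation_grid(origin[1], origin[2], cell,
                 matrix(as.integer(value), n, n))
}

ridge_test_terrain <- function() {
  synth_terrain(bounds = list(lon = c(0, 1), lat = c(0, 1)),
                resolution = 120,
                spec = list(amplitude = 1200, ridge_lat = 0.5,
                            ridge_width = 0.1))
}

# exact raw moments of U(0, 2): mu_k = 2^k / (k + 1)
uniform02_moments <- function(upto) 2^(0:upto) / (1:(upto + 1))

# exact raw moments of N(mean, sd) up to order 6
normal_moments <- function(mean, sd, upto) {
  stopifnot(upto <= 6)
  s2 <- sd^2
  mom <- c(1, mean,
           mean^2 + s2,
           mean^3 + 3 * mean * s2,
           mean^4 + 6 * mean^2 * s2 + 3 * s2^2,
           mean^5 + 10 * mean^3 * s2 + 15 * mean * s2^2,
           mean^6 + 15 * mean^4 * s2 + 45 * mean^2 * s2^2 + 15 * s2^3)
  mom[1:(upto + 1)]
}

# the ridge-invasion demo is expensive; run it (and its UQ companion) once
# per test session and cache
demo_cache <- new.env(parent = emptyenv())

demo_simulation <- function() {
  if (is.null(demo_cache$sim)) {
    sc <- ridge_demo_scenario()
    res <- run_simulation(sc$mesh, sc$coeffs, sc$u0, dt = sc$dt,
                          T_end = sc$T_end, threshold = sc$threshold,
                          probes = sc$probes, mass = sc$mass)
    demo_cache$scenario <- sc
    demo_cache$sim <- res
  }
  list(scenario = demo_cache$scenario, result = demo_cache$sim)
}

demo_uq <- function() {
  if (is.null(demo_cache$uq)) {
    d <- demo_simulation()
    inputs <- synth_histograms(reference_uq_inputs(), n = 10000L, seed = 1L)
    demo_cache$uq <- run_uq(d$scenario$mesh, inputs, u0 = d$scenario$u0,
                            dt = d$scenario$dt, T_end = d$scenario$T_end,
                            threshold = d$scenario$threshold,
                            probes = d$scenario$probes, level = 1L,
                            n_mc = 2e4, seed = 1L, mass = d$scenario$mass)
  }
  list(scenario = demo_cache$scenario, uq = demo_cache$uq)
}

# minimal flat-terrain scenario config for pipeline tests
micro_config <- function(tmp = tempdir()) {
  list(
    domain = list(lon = c(0, 0.4), lat = c(0, 0.4), buffer = 0.05),
    terrain = list(synthetic = list(amplitude = 0, resolution = 240,
                                    seed = 1)),
    mesh = list(background_size = 0.1, roi_size = 0.08,
                gradient_passes = 0),
    coefficients = list(nu0 = 5e-4, alpha = 1),
    initial = list(center = c(0.1, 0.1), radius = 0.08, amplitude = 10),
    time = list(dt_months = 0.5, horizon_years = 2, stride = 10,
                threshold = 1),
    probes = list(near = c(0.15, 0.12), far = c(0.35, 0.35))
  )
}
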