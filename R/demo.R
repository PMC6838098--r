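# Bundled "ridge invasion" demonstration: a synthetic landscape shaped like
# the reference geography - an east-west mountain ridge tall enough to be
# uninhabitable at its crest (above the 1000 m line of the carrying-capacity
# law), interrupted by a single north-south valley - with the initial colony
# north-east of the ridge. The species must travel west along the ridge and
# cross south through the valley gap.

#' Synthetic ridge-with-valley terrain for the demo scenario
#'
#' @param seed seed for the (by default absent) noise component
#' @param resolution cell size in arc-seconds
#' @param noise_sd additive elevation noise in metres
#' @return an [elevation_grid()]
#' @export
ridge_demo_terrain <- function(seed = 1L, resolution = 60, noise_sd = 0) {
  synth_terrain(
    bounds = list(lon = c(-0.15, 1.35), lat = c(-0.15, 1.35)),
    resolution = resolution,
    spec = list(amplitude = 1500, ridge_lat = 0.55, ridge_width = 0.09,
                valley_lon = 0.35, valley_width = 0.06,
                noise_sd = noise_sd),
    seed = seed)
}

#' Assemble the bundled ridge-invasion demo scenario
#'
#' Builds terrain, mesh (region of interest plus a buffer margin against
#' boundary artifacts, with gradient-driven refinement on the ridge flanks)
#' and the reference coefficient set (constant diffusion, elevation-driven
#' carrying capacity), with the colony north of the ridge and three probes.
#'
#' @param seed terrain seed
#' @param background_size background target edge length (deg)
#' @param roi_size target edge length inside the region of interest (deg)
#' @param buffer buffer margin around the region of interest (deg)
#' @param gradient_threshold elevation-gradient refinement threshold (m/deg)
#' @param gradient_passes refinement passes
#' @param T_end simulation horizon in years
#' @return list with `terrain`, `mesh`, `coeffs`, `u0`, `probes`, `dt`,
#'   `T_end`, `threshold`, `colony`
#' @export
ridge_demo_scenario <- function(seed = 1L, background_size = 0.1,
                                roi_size = 0.07, buffer = 0.1,
                                gradient_threshold = 2500,
                                gradient_passes = 1L, T_end = 14) {
  terrain <- ridge_demo_terrain(seed = seed)
  roi <- cbind(c(0, 1.2, 1.2, 0), c(0, 0, 1.2, 1.2))
  domain <- c(-buffer, 1.2 + buffer, -buffer, 1.2 + buffer)
  mesh <- generate_mesh(domain, background_size, roi = roi,
                        roi_size = roi_size)
  mesh <- attach_elevation(mesh, terrain)
  mesh <- gradient_refine(mesh, terrain, threshold = gradient_threshold,
                          passes = gradient_passes)
  coeffs <- elevation_scenario_coefficients(mesh, alpha = 1, nu0 = 5e-4)
  colony <- list(center = c(0.9, 0.95), radius = 0.15, amplitude = 10)
  u0 <- initial_condition(mesh, colony$center, colony$radius,
                          colony$amplitude)
  probes <- list(north = c(0.6, 0.9), gap = c(0.35, 0.55),
                 south = c(0.8, 0.2))
  list(terrain = terrain, mesh = mesh, coeffs = coeffs, u0 = u0,
       probes = probes, dt = 1 / 120, T_end = T_end, threshold = 1,
       mass = "lumped", colony = colony)
}
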