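#' Elevation-dependent carrying capacity
#'
#' The carrying capacity law used throughout the reference scenario:
#' `gamma = alpha * (10 - z/100)`, i.e. 10 density units at sea level,
#' decreasing by 1 unit per 100 m of elevation and crossing zero at 1000 m.
#' The value is deliberately not clamped at zero: negative values model
#' terrain that is actively hostile (the reaction term `u(gamma - u)` then
#' strictly damps any population there), rather than merely neutral.
#'
#' @param z elevation in metres (any real, vectorized)
#' @param alpha dimensionless scale on the whole law (default 1)
#' @return carrying capacity in density units
#' @export
elevation_gamma <- function(z, alpha = 1) {
  alpha * (10 - z / 100)
}

#' Model coefficient set
#'
#' Bundles the four coefficient fields of the dispersal PDE
#' `du/dt - div(nu grad u) + b . grad u + u(u - gamma) = f`:
#' diffusion `nu` (deg^2/yr), transport `b` (deg/yr vector), carrying
#' capacity `gamma` and source `f` (density units). Each entry may be a
#' constant, a per-node (for `gamma`, `f`) or per-triangle (for `nu`, `b`)
#' numeric vector, or a function `(pts, t)` evaluated at nodes
#' (`gamma`, `f`) or element centroids (`nu`, `b`); `b` as a function must
#' return an n x 2 matrix. Masks added via [apply_masks()] modify the
#' discretized fields.
#'
#' @param nu diffusion coefficient (>= 0), deg^2 per year
#' @param b transport field, deg per year
#' @param gamma carrying capacity, density units
#' @param f source term, density units per year
#' @param alpha dimensionless carrying-capacity scale (bookkeeping only;
#'   the scale must already be included in `gamma`)
#' @param time_dependent set `TRUE` if any coefficient genuinely depends on
#'   `t`, forcing per-step re-assembly during simulation
#' @return object of class `coefficient_set`
#' @export
coefficient_set <- function(nu = 5e-4, b = c(0, 0), gamma = 10, f = 0,
                            alpha = 1, time_dependent = FALSE) {
  structure(list(nu = nu, b = b, gamma = gamma, f = f, alpha = alpha,
                 masks = list(), time_dependent = time_dependent),
            class = "coefficient_set")
}

#' @export
print.coefficient_set <- function(x, ...) {
  fmt <- function(v) if (is.function(v)) "function(pts, t)"
    else if (length(v) <= 2) paste(signif(v, 4), collapse = ", ")
    else sprintf("field[%d]", length(v))
  cat("<coefficient_set>\n",
      sprintf("  nu    = %s deg^2/yr\n", fmt(x$nu)),
      sprintf("  b     = (%s) deg/yr\n", fmt(x$b)),
      sprintf("  gamma = %s\n", fmt(x$gamma)),
      sprintf("  f     = %s\n", fmt(x$f)),
      sprintf("  %d mask(s), time_dependent = %s\n",
              length(x$masks), x$time_dependent), sep = "")
  invisible(x)
}

#' Overlay heterogeneity masks on a coefficient set
#'
#' Each mask names a set of mesh nodes and multiplies the carrying capacity
#' and/or diffusion coefficient there; lake masks force the carrying
#' capacity to exactly zero. Masks are applied during discretization
#' ([eval_coefficients()]): `gamma` is modified on the mask nodes, `nu` on
#' triangles whose three vertices all belong to the mask. Disjoint masks
#' commute.
#'
#' @param base a [coefficient_set()]
#' @param masks list of masks, each a list with `nodes` (integer node
#'   indices) and optional `gamma_factor` (default 1), `nu_factor`
#'   (default 1), `lake` (logical, default `FALSE`)
#' @param n_nodes optional node count for immediate index validation
#' @return the coefficient set with masks appended
#' @export
apply_masks <- function(base, masks, n_nodes = NULL) {
  stopifnot(inherits(base, "coefficient_set"))
  for (m in masks) {
    if (is.null(m$nodes)) stop("each mask needs a 'nodes' component")
    if (!is.null(n_nodes) && (length(m$nodes) > 0) &&
        (min(m$nodes) < 1 || max(m$nodes) > n_nodes))
      stop("index error: mask refers to node outside 1..", n_nodes)
  }
  base$masks <- c(base$masks, masks)
  base
}

#' Reference scenario coefficients: constant diffusion, elevation-driven
#' carrying capacity
#'
#' Constant diffusion `nu0`, no transport, no source, and carrying capacity
#' [elevation_gamma()] evaluated at each node's elevation scaled by `alpha`.
#'
#' @param mesh a [tri_mesh()] with elevation attached
#' @param alpha dimensionless carrying-capacity scale
#' @param nu0 diffusion coefficient in deg^2 per year
#' @return a [coefficient_set()] with a per-node `gamma` field
#' @export
elevation_scenario_coefficients <- function(mesh, alpha = 1, nu0 = 5e-4) {
  if (is.null(mesh$node_elevation))
    stop("state error: mesh has no elevations; call attach_elevation() first")
  coefficient_set(nu = nu0, b = c(0, 0),
                  gamma = elevation_gamma(mesh$node_elevation, alpha),
                  f = 0, alpha = alpha)
}

# Discretize a coefficient set on a mesh at time t:
# nu, b at element centroids (per-triangle), gamma, f at nodes.
eval_coefficients <- function(coeffs, mesh, t = 0) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$triangles)
  cen <- tri_centroids(mesh)
  as_field <- function(v, pts, len, what) {
    if (is.function(v)) v <- v(pts, t)
    if (length(v) == 1) v <- rep(as.numeric(v), len)
    if (length(v) != len)
      stop(sprintf("coefficient %s has length %d; expected %d",
                   what, length(v), len))
    as.numeric(v)
  }
  nu <- as_field(coeffs$nu, cen, m, "nu")
  gamma <- as_field(coeffs$gamma, mesh$nodes, n, "gamma")
  f <- as_field(coeffs$f, mesh$nodes, n, "f")
  bv <- coeffs$b
  if (is.function(bv)) bv <- bv(cen, t)
  if (is.null(dim(bv))) {
    if (length(bv) != 2) stop("constant b must have two components")
    bv <- matrix(bv, nrow = m, ncol = 2, byrow = TRUE)
  }
  if (nrow(bv) != m) stop("per-triangle b must have one row per triangle")
  for (msk in coeffs$masks) {
    idx <- msk$nodes
    if (length(idx) == 0) next
    if (min(idx) < 1 || max(idx) > n)
      stop("index error: mask refers to node outside 1..", n)
    gf <- if (is.null(msk$gamma_factor)) 1 else msk$gamma_factor
    nf <- if (is.null(msk$nu_factor)) 1 else msk$nu_factor
    gamma[idx] <- gamma[idx] * gf
    if (isTRUE(msk$lake)) gamma[idx] <- 0
    if (nf != 1) {
      inmask <- rep(FALSE, n); inmask[idx] <- TRUE
      tri_in <- inmask[mesh$triangles[, 1]] & inmask[mesh$triangles[, 2]] &
                inmask[mesh$triangles[, 3]]
      nu[tri_in] <- nu[tri_in] * nf
    }
  }
  list(nu = nu, b = bv, gamma = gamma, f = f)
}
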