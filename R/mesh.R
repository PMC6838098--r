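#' Triangular mesh container
#'
#' Planar conforming triangulation in geographic degree coordinates
#' (lon = x, lat = y), optionally carrying per-node elevation. Triangles are
#' stored counter-clockwise.
#'
#' @param nodes N x 2 numeric matrix of (lon, lat)
#' @param triangles M x 3 integer matrix of node indices
#' @param node_elevation optional numeric vector, metres, one per node
#' @param roi optional region-of-interest polygon (K x 2 matrix, degrees)
#' @return object of class `tri_mesh`
#' @export
tri_mesh <- function(nodes, triangles, node_elevation = NULL, roi = NULL) {
  nodes <- as.matrix(nodes); storage.mode(nodes) <- "double"
  triangles <- as.matrix(triangles); storage.mode(triangles) <- "integer"
  dimnames(nodes) <- NULL; dimnames(triangles) <- NULL
  if (ncol(nodes) != 2 || ncol(triangles) != 3)
    stop("nodes must be N x 2 and triangles M x 3")
  if (min(triangles) < 1 || max(triangles) > nrow(nodes))
    stop("triangle refers to a non-existent node index")
  triangles <- orient_ccw(nodes, triangles)
  if (!is.null(node_elevation) && length(node_elevation) != nrow(nodes))
    stop("node_elevation must have one entry per node")
  m <- structure(
    list(nodes = nodes, triangles = triangles,
         node_elevation = node_elevation,
         boundary = rep(FALSE, nrow(nodes)),
         green = rep(FALSE, nrow(triangles)),
         roi = roi),
    class = "tri_mesh")
  m$boundary <- boundary_nodes(m)
  m
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d nodes, %d triangles, area %.6g deg^2%s\n",
              nrow(x$nodes), nrow(x$triangles), sum(tri_areas(x)),
              if (is.null(x$node_elevation)) "" else ", with elevation"))
  invisible(x)
}

orient_ccw <- function(nodes, triangles) {
  a <- signed_areas(nodes, triangles)
  flip <- a < 0
  if (any(flip)) {
    tmp <- triangles[flip, 2]
    triangles[flip, 2] <- triangles[flip, 3]
    triangles[flip, 3] <- tmp
  }
  triangles
}

signed_areas <- function(nodes, triangles) {
  x <- matrix(nodes[triangles, 1], ncol = 3)
  y <- matrix(nodes[triangles, 2], ncol = 3)
  0.5 * ((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
         (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]))
}

#' Triangle areas of a mesh
#' @param mesh a [tri_mesh()]
#' @return numeric vector of (positive) triangle areas in deg^2
#' @export
tri_areas <- function(mesh) abs(signed_areas(mesh$nodes, mesh$triangles))

#' Triangle centroids
#' @param mesh a [tri_mesh()]
#' @return M x 2 matrix of centroid coordinates
#' @export
tri_centroids <- function(mesh) {
  x <- matrix(mesh$nodes[mesh$triangles, 1], ncol = 3)
  y <- matrix(mesh$nodes[mesh$triangles, 2], ncol = 3)
  cbind(rowMeans(x), rowMeans(y))
}

# Sorted-pair edge keys for all 3M triangle edges (double-precision exact).
edge_keys <- function(triangles, n_nodes) {
  e1 <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  lo <- pmin(e1[, 1], e1[, 2]); hi <- pmax(e1[, 1], e1[, 2])
  list(key = as.numeric(lo) * (n_nodes + 1) + hi, lo = lo, hi = hi)
}

# Nodes lying on the mesh boundary (endpoint of an edge used by one triangle).
boundary_nodes <- function(mesh) {
  ek <- edge_keys(mesh$triangles, nrow(mesh$nodes))
  cnt <- table(ek$key)
  bkey <- as.numeric(names(cnt)[cnt == 1])
  onb <- ek$key %in% bkey
  flag <- rep(FALSE, nrow(mesh$nodes))
  flag[c(ek$lo[onb], ek$hi[onb])] <- TRUE
  flag
}

#' Minimum interior angle of each triangle (degrees)
#' @param mesh a [tri_mesh()]
#' @return numeric vector of length M
#' @export
tri_min_angles <- function(mesh) {
  p <- mesh$nodes; t <- mesh$triangles
  l2 <- function(i, j) (p[t[, i], 1] - p[t[, j], 1])^2 +
                       (p[t[, i], 2] - p[t[, j], 2])^2
  a2 <- l2(2, 3); b2 <- l2(1, 3); c2 <- l2(1, 2)
  ang <- function(o2, u2, v2) acos(pmin(pmax((u2 + v2 - o2) /
                                             (2 * sqrt(u2 * v2)), -1), 1))
  deg <- 180 / pi
  pmin(ang(a2, b2, c2), ang(b2, a2, c2), ang(c2, a2, b2)) * deg
}

is_rectangle <- function(poly) {
  if (nrow(poly) != 4) return(FALSE)
  xs <- sort(unique(poly[, 1])); ys <- sort(unique(poly[, 2]))
  length(xs) == 2 && length(ys) == 2 &&
    all(poly[, 1] %in% xs) && all(poly[, 2] %in% ys)
}

polygon_area <- function(poly) {
  n <- nrow(poly); j <- c(2:n, 1)
  0.5 * abs(sum(poly[, 1] * poly[j, 2] - poly[j, 1] * poly[, 2]))
}

is_convex <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1); k <- c(3:n, 1, 2)
  cr <- (poly[j, 1] - poly[, 1]) * (poly[k, 2] - poly[j, 2]) -
        (poly[j, 2] - poly[, 2]) * (poly[k, 1] - poly[j, 1])
  all(cr >= -1e-14 * max(abs(cr))) || all(cr <= 1e-14 * max(abs(cr)))
}

as_polygon <- function(domain) {
  if (is.null(dim(domain)) && length(domain) == 4) {
    domain <- cbind(c(domain[1], domain[2], domain[2], domain[1]),
                    c(domain[3], domain[3], domain[4], domain[4]))
  }
  domain <- as.matrix(domain)
  if (nrow(domain) > 1 &&
      all(abs(domain[1, ] - domain[nrow(domain), ]) < 1e-15))
    domain <- domain[-nrow(domain), , drop = FALSE]
  if (nrow(domain) < 3 || polygon_area(domain) < 1e-12)
    stop("geometry error: domain polygon is degenerate")
  domain
}

#' Points-in-polygon test
#' @param points n x 2 matrix (lon, lat)
#' @param poly polygon vertices, K x 2
#' @return logical vector
#' @export
in_polygon <- function(points, poly) {
  points <- coerce_points(points)
  mgcv::in.out(rbind(as.matrix(poly), poly[1, ]), points)
}

#' Generate a triangular mesh of a polygonal domain
#'
#' Builds a conforming triangulation whose local edge length follows a target
#' size field, via a structured base grid (axis-aligned rectangular domains)
#' or a centroid fan (convex polygons) followed by iterative red-green
#' refinement of triangles whose longest edge exceeds the local target.
#'
#' @param domain rectangle `c(lon_min, lon_max, lat_min, lat_max)` or a
#'   convex polygon as a K x 2 matrix
#' @param size_field target edge length in degrees: a positive scalar or a
#'   function `(lon, lat) -> length` evaluated at triangle centroids
#' @param roi optional region-of-interest polygon stored with the mesh
#' @param roi_size optional smaller target edge length enforced inside `roi`
#' @param max_passes refinement pass cap
#' @return a [tri_mesh()]
#' @export
generate_mesh <- function(domain, size_field, roi = NULL, roi_size = NULL,
                          max_passes = 30L) {
  poly <- as_polygon(domain)
  if (!is_convex(poly))
    stop("geometry error: domain polygon must be simple and convex")
  size_fun <- if (is.function(size_field)) size_field else {
    h <- as.numeric(size_field)
    if (h <= 0) stop("size_field must be strictly positive")
    function(lon, lat) rep(h, length(lon))
  }
  target_at <- function(pts) {
    h <- size_fun(pts[, 1], pts[, 2])
    if (any(h <= 0)) stop("size_field must be strictly positive")
    if (!is.null(roi) && !is.null(roi_size)) {
      inside <- in_polygon(pts, roi)
      h[inside] <- pmin(h[inside], roi_size)
    }
    h
  }
  mesh <- base_triangulation(poly, target_at)
  mesh$roi <- roi
  for (pass in seq_len(max_passes)) {
    cen <- tri_centroids(mesh)
    long <- longest_edges(mesh)
    flag <- long > target_at(cen) * (1 + 1e-9)
    if (!any(flag)) break
    mesh <- refine_triangles(mesh, flag)
  }
  mesh
}

longest_edges <- function(mesh) {
  p <- mesh$nodes; t <- mesh$triangles
  l <- function(i, j) sqrt((p[t[, i], 1] - p[t[, j], 1])^2 +
                           (p[t[, i], 2] - p[t[, j], 2])^2)
  pmax(l(1, 2), l(2, 3), l(3, 1))
}

base_triangulation <- function(poly, target_at) {
  if (is_rectangle(poly)) {
    xr <- range(poly[, 1]); yr <- range(poly[, 2])
    # coarse structured start near the largest admissible cell size
    h0 <- max(target_at(cbind(mean(xr), mean(yr))),
              target_at(poly))
    nx <- max(1L, ceiling(diff(xr) / h0))
    ny <- max(1L, ceiling(diff(yr) / h0))
    xs <- seq(xr[1], xr[2], length.out = nx + 1)
    ys <- seq(yr[1], yr[2], length.out = ny + 1)
    nodes <- cbind(rep(xs, times = ny + 1), rep(ys, each = nx + 1))
    id <- function(i, j) (j - 1L) * (nx + 1L) + i
    i <- rep(seq_len(nx), times = ny); j <- rep(seq_len(ny), each = nx)
    n00 <- id(i, j); n10 <- id(i + 1L, j)
    n01 <- id(i, j + 1L); n11 <- id(i + 1L, j + 1L)
    tris <- rbind(cbind(n00, n10, n11), cbind(n00, n11, n01))
    tri_mesh(nodes, tris)
  } else {
    cen <- colMeans(poly)
    nodes <- rbind(poly, cen)
    n <- nrow(poly); ci <- n + 1L
    tris <- cbind(seq_len(n), c(2:n, 1L), rep(ci, n))
    tri_mesh(nodes, tris)
  }
}

#' Red-green refinement of flagged triangles
#'
#' Flagged triangles are subdivided regularly ("red", four similar children
#' through the edge midpoints); neighbours left with one hanging node are
#' bisected ("green"); neighbours with two or more hanging nodes, and green
#' triangles touched again, are promoted to red so element quality cannot
#' degrade across passes. The result is conforming (no hanging nodes) and
#' counter-clockwise.
#'
#' @param mesh a [tri_mesh()]
#' @param flag logical vector, length = number of triangles
#' @return refined [tri_mesh()]
#' @export
refine_triangles <- function(mesh, flag) {
  stopifnot(length(flag) == nrow(mesh$triangles))
  if (!any(flag)) return(mesh)
  t <- mesh$triangles; nN <- nrow(mesh$nodes); nT <- nrow(t)
  ek <- edge_keys(t, nN)
  key <- matrix(ek$key, nrow = nT) # columns: edge (1,2), (2,3), (3,1)
  red <- as.logical(flag)
  # edge lengths by local edge position (1,2), (2,3), (3,1): green bisection
  # is only allowed across a triangle's longest edge (else promote to red),
  # which keeps element quality bounded across passes
  p <- mesh$nodes
  elen <- cbind(
    sqrt((p[t[, 1], 1] - p[t[, 2], 1])^2 + (p[t[, 1], 2] - p[t[, 2], 2])^2),
    sqrt((p[t[, 2], 1] - p[t[, 3], 1])^2 + (p[t[, 2], 2] - p[t[, 3], 2])^2),
    sqrt((p[t[, 3], 1] - p[t[, 1], 1])^2 + (p[t[, 3], 2] - p[t[, 1], 2])^2))
  max_elen <- pmax(elen[, 1], elen[, 2], elen[, 3])
  repeat {
    split_keys <- unique(as.numeric(key[red, ]))
    nsplit <- matrix(key %in% split_keys, nrow = nT)
    cnt <- rowSums(nsplit)
    promote <- (!red) & (cnt >= 2 | (mesh$green & cnt >= 1))
    one <- which(!red & !promote & cnt == 1)
    if (length(one)) {
      which_e <- max.col(nsplit[one, , drop = FALSE])
      not_longest <- elen[cbind(one, which_e)] < max_elen[one] * (1 - 1e-9)
      promote[one[not_longest]] <- TRUE
    }
    if (!any(promote)) break
    red <- red | promote
  }
  # midpoint node per split edge
  split_keys <- sort(unique(as.numeric(key[red, ])))
  lo <- floor(split_keys / (nN + 1)); hi <- split_keys - lo * (nN + 1)
  mid_xy <- (mesh$nodes[lo, , drop = FALSE] + mesh$nodes[hi, , drop = FALSE]) / 2
  mid_id <- nN + seq_along(split_keys)
  mid_of <- function(k) mid_id[match(k, split_keys)]
  nodes <- rbind(mesh$nodes, mid_xy)
  elev <- if (is.null(mesh$node_elevation)) NULL else
    c(mesh$node_elevation, (mesh$node_elevation[lo] + mesh$node_elevation[hi]) / 2)

  nsplit <- matrix(key %in% split_keys, nrow = nT)
  cnt <- rowSums(nsplit)
  keep <- which(cnt == 0)
  out_t <- list(t[keep, , drop = FALSE])
  out_g <- list(mesh$green[keep])

  ired <- which(red)
  if (length(ired)) {
    m12 <- mid_of(key[ired, 1]); m23 <- mid_of(key[ired, 2])
    m31 <- mid_of(key[ired, 3])
    out_t <- c(out_t, list(
      cbind(t[ired, 1], m12, m31), cbind(m12, t[ired, 2], m23),
      cbind(m31, m23, t[ired, 3]), cbind(m12, m23, m31)))
    out_g <- c(out_g, rep(list(mesh$green[ired]), 4))
  }
  igreen <- which(!red & cnt == 1)
  if (length(igreen)) {
    which_e <- max.col(nsplit[igreen, , drop = FALSE])
    # edge e connects vertices e and e%%3+1; opposite vertex is (e+1)%%3+1
    v1 <- t[cbind(igreen, which_e)]
    v2 <- t[cbind(igreen, which_e %% 3L + 1L)]
    vo <- t[cbind(igreen, (which_e + 1L) %% 3L + 1L)]
    m <- mid_of(key[cbind(igreen, which_e)])
    out_t <- c(out_t, list(cbind(v1, m, vo), cbind(m, v2, vo)))
    out_g <- c(out_g, rep(list(rep(TRUE, length(igreen))), 2))
  }
  tris <- do.call(rbind, out_t)
  res <- tri_mesh(nodes, tris, node_elevation = elev, roi = mesh$roi)
  res$green <- unlist(out_g) # tri_mesh() keeps triangle row order
  res
}

#' Uniform (red) refinement of the whole mesh
#' @param mesh a [tri_mesh()]
#' @param times number of uniform refinement sweeps
#' @return refined [tri_mesh()]
#' @export
uniform_refine <- function(mesh, times = 1L) {
  for (i in seq_len(times))
    mesh <- refine_triangles(mesh, rep(TRUE, nrow(mesh$triangles)))
  mesh
}

#' Attach interpolated elevation to mesh nodes
#'
#' @param mesh a [tri_mesh()]
#' @param grid an [elevation_grid()] covering all mesh nodes
#' @return the mesh with `node_elevation` set (other fields unchanged)
#' @export
attach_elevation <- function(mesh, grid) {
  mesh$node_elevation <- elevation_at(grid, mesh$nodes)
  mesh
}

#' Per-triangle elevation gradient magnitude
#'
#' Gradient of the piecewise-linear interpolant of node elevations, in
#' metres per degree.
#' @param mesh a [tri_mesh()] with elevation attached
#' @return numeric vector of length M
#' @export
elevation_gradients <- function(mesh) {
  if (is.null(mesh$node_elevation))
    stop("mesh has no elevation attached; call attach_elevation() first")
  g <- p1_gradients(mesh)
  z <- matrix(mesh$node_elevation[mesh$triangles], ncol = 3)
  gx <- rowSums(g$gx * z); gy <- rowSums(g$gy * z)
  sqrt(gx^2 + gy^2)
}

#' Gradient-driven mesh refinement
#'
#' Splits every triangle whose elevation-gradient magnitude exceeds a
#' threshold, re-attaching elevations after each pass, so the mesh is finer
#' along steep terrain (valley sides, ridge flanks).
#'
#' @param mesh a [tri_mesh()]
#' @param grid the [elevation_grid()] supplying elevations
#' @param threshold gradient threshold in metres per degree (> 0)
#' @param passes number of refinement passes (>= 1)
#' @return refined [tri_mesh()] with elevation attached
#' @export
gradient_refine <- function(mesh, grid, threshold = 2000, passes = 1L) {
  if (threshold <= 0) stop("threshold must be positive")
  if (passes < 1) stop("passes must be >= 1")
  if (is.null(mesh$node_elevation)) mesh <- attach_elevation(mesh, grid)
  for (p in seq_len(passes)) {
    flag <- elevation_gradients(mesh) > threshold
    if (!any(flag)) break
    mesh <- refine_triangles(mesh, flag)
    mesh <- attach_elevation(mesh, grid)
  }
  mesh
}
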