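# P1 Lagrange assembly over a tri_mesh. Element conventions: on triangle T
# with CCW vertices p1 p2 p3 and area |T|, the barycentric basis lambda_a is
# linear with constant gradient; nu and b are sampled at the centroid
# (one-point rule, exact since the remaining integrand is constant/linear),
# the cubic reaction integrand uses a 4-point degree-3 rule.

# Constant P1 basis gradients per triangle: lists gx, gy of M x 3 matrices.
p1_gradients <- function(mesh) {
  t <- mesh$triangles
  x <- matrix(mesh$nodes[t, 1], ncol = 3)
  y <- matrix(mesh$nodes[t, 2], ncol = 3)
  a2 <- (x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
        (x[, 3] - x[, 1]) * (y[, 2] - y[, 1]) # 2 * signed area (> 0, CCW)
  gx <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / a2
  gy <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / a2
  list(gx = gx, gy = gy, area = a2 / 2)
}

check_degenerate <- function(area) {
  bad <- which(area < 1e-14)
  if (length(bad))
    stop("geometry error: degenerate triangle ", bad[1],
         " (area ", format(area[bad[1]]), ")")
}

element_triplets <- function(mesh, elem_fun) {
  t <- mesh$triangles
  ii <- jj <- xx <- vector("list", 9)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    k <- k + 1
    ii[[k]] <- t[, a]; jj[[k]] <- t[, b]; xx[[k]] <- elem_fun(a, b)
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                       dims = rep(nrow(mesh$nodes), 2))
}

#' Assemble the P1 mass matrix
#'
#' Consistent mass matrix `M_ij = int phi_j phi_i dx`; the element block on a
#' triangle of area `|T|` is `(|T|/12) [[2,1,1],[1,2,1],[1,1,2]]` (exact for
#' P1). With `lumped = TRUE` the row-sum lumped diagonal is returned instead.
#'
#' @param mesh a [tri_mesh()]
#' @param lumped return the lumped (diagonal) mass matrix
#' @return sparse symmetric N x N matrix
#' @export
assemble_mass <- function(mesh, lumped = FALSE) {
  g <- p1_gradients(mesh)
  check_degenerate(g$area)
  if (lumped) {
    t <- mesh$triangles
    d <- numeric(nrow(mesh$nodes))
    for (a in 1:3) d <- d + tabulate_add(t[, a], g$area / 3, nrow(mesh$nodes))
    return(Matrix::Diagonal(x = d))
  }
  element_triplets(mesh, function(a, b) g$area / 12 * (1 + (a == b)))
}

tabulate_add <- function(idx, vals, n) {
  out <- numeric(n)
  agg <- rowsum(vals, idx, reorder = FALSE)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' Assemble the P1 stiffness matrix
#'
#' `A_ij = int nu(x) grad phi_j . grad phi_i dx` with the diffusion
#' coefficient sampled at element centroids. The result is symmetric
#' positive semi-definite with the constant vector in its kernel
#' (pure-Neumann problem).
#'
#' @param mesh a [tri_mesh()]
#' @param nu diffusion coefficient: scalar, per-triangle vector, or
#'   function `(pts, t)`
#' @param t time passed to coefficient functions
#' @return sparse symmetric N x N matrix
#' @export
assemble_stiffness <- function(mesh, nu = 1, t = 0) {
  g <- p1_gradients(mesh)
  check_degenerate(g$area)
  m <- nrow(mesh$triangles)
  if (is.function(nu)) nu <- nu(tri_centroids(mesh), t)
  nu <- if (length(nu) == 1) rep(as.numeric(nu), m) else as.numeric(nu)
  if (length(nu) != m) stop("nu must be scalar or one value per triangle")
  if (any(nu < 0))
    stop("coefficient error: negative diffusion coefficient at triangle ",
         which(nu < 0)[1])
  element_triplets(mesh, function(a, b)
    nu * g$area * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b]))
}

#' Assemble the P1 transport matrix
#'
#' `B_ij = int (b(x) . grad phi_j) phi_i dx` with the velocity sampled at
#' element centroids and `int_T phi_i = |T|/3` used exactly. Satisfies
#' `B 1 = 0` since the basis gradients sum to zero on each element.
#'
#' @param mesh a [tri_mesh()]
#' @param b transport field: length-2 constant, M x 2 matrix, or function
#'   `(pts, t)` returning an M x 2 matrix
#' @param t time passed to coefficient functions
#' @return sparse N x N matrix (nonsymmetric in general)
#' @export
assemble_transport <- function(mesh, b = c(0, 0), t = 0) {
  g <- p1_gradients(mesh)
  check_degenerate(g$area)
  m <- nrow(mesh$triangles)
  if (is.function(b)) b <- b(tri_centroids(mesh), t)
  if (is.null(dim(b))) b <- matrix(b, nrow = m, ncol = 2, byrow = TRUE)
  if (nrow(b) != m || ncol(b) != 2) stop("b must be M x 2")
  element_triplets(mesh, function(a, b_) {
    (b[, 1] * g$gx[, b_] + b[, 2] * g$gy[, b_]) * g$area / 3
  })
}

# Degree-3 quadrature on the reference triangle in barycentric coordinates
# (exact for cubic polynomials; the reaction integrand (gamma_h-u_h)u_h phi_i
# is cubic when u_h, gamma_h are P1).
REACTION_QUAD <- list(
  bary = rbind(c(1, 1, 1) / 3,
               c(3, 1, 1) / 5,
               c(1, 3, 1) / 5,
               c(1, 1, 3) / 5),
  w = c(-27, 25, 25, 25) / 48)

#' Assemble the nonlinear reaction load vector
#'
#' `F_i = int (gamma(x,t) - u_h) u_h phi_i dx + int f(x,t) phi_i dx`, with
#' `u_h` the P1 interpolant of the nodal vector `u`, `gamma` interpolated to
#' P1 nodal values, and a 4-point degree-3 triangle rule (exact for the
#' cubic integrand).
#'
#' @param mesh a [tri_mesh()]
#' @param u nodal density vector (length N)
#' @param gamma carrying capacity: scalar, per-node vector, or function
#'   `(pts, t)`
#' @param f source term: scalar, per-node vector, or function `(pts, t)`
#' @param t time passed to coefficient functions
#' @param geom optional cached [p1_gradients()] output for repeated calls
#' @return numeric load vector of length N
#' @export
reaction_load <- function(mesh, u, gamma = 10, f = 0, t = 0, geom = NULL) {
  n <- nrow(mesh$nodes)
  if (length(u) != n)
    stop(sprintf("dimension error: u has length %d, mesh has %d nodes",
                 length(u), n))
  if (is.null(geom)) geom <- p1_gradients(mesh)
  check_degenerate(geom$area)
  tt <- mesh$triangles
  as_nodal <- function(v, what) {
    if (is.function(v)) v <- v(mesh$nodes, t)
    if (length(v) == 1) v <- rep(as.numeric(v), n)
    if (length(v) != n) stop("dimension error: ", what,
                             " must be scalar or one value per node")
    as.numeric(v)
  }
  gam <- as_nodal(gamma, "gamma")
  ff <- as_nodal(f, "f")
  U <- matrix(u[tt], ncol = 3)
  G <- matrix(gam[tt], ncol = 3)
  FF <- matrix(ff[tt], ncol = 3)
  Q <- REACTION_QUAD$bary; w <- REACTION_QUAD$w
  out <- numeric(n)
  for (a in 1:3) {
    acc <- 0
    for (q in seq_along(w)) {
      uq <- U %*% Q[q, ]; gq <- G %*% Q[q, ]; fq <- FF %*% Q[q, ]
      acc <- acc + w[q] * Q[q, a] * ((gq - uq) * uq + fq)
    }
    out <- out + tabulate_add(tt[, a], geom$area * as.numeric(acc), n)
  }
  out
}

#' Assemble the full semi-discrete system
#'
#' Convenience wrapper returning the mass, stiffness and transport matrices
#' for a coefficient set discretized at time `t`, plus the discretized
#' coefficient fields.
#'
#' @param mesh a [tri_mesh()]
#' @param coeffs a [coefficient_set()]
#' @param t assembly time
#' @param lumped use the lumped (diagonal) mass matrix
#' @return object of class `assembled_system`: list with `M`, `A`, `B`
#'   (sparse, `B = NULL` when the transport field is identically zero),
#'   `N`, and `fields` (the [eval_coefficients()] output)
#' @export
assemble_system <- function(mesh, coeffs, t = 0, lumped = FALSE) {
  fields <- eval_coefficients(coeffs, mesh, t)
  M <- assemble_mass(mesh, lumped = lumped)
  A <- assemble_stiffness(mesh, fields$nu)
  B <- if (all(fields$b == 0)) NULL else assemble_transport(mesh, fields$b)
  structure(list(M = M, A = A, B = B, N = nrow(mesh$nodes), fields = fields),
            class = "assembled_system")
}

#' Dump a sparse matrix in MatrixMarket coordinate format
#' @param mat a sparse matrix
#' @param path output file
#' @export
write_matrix_market <- function(mat, path) {
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"), path)
  invisible(path)
}
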