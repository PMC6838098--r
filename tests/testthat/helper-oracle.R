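# Independent quadrature oracle for the P1 assemblies: a 16-point Gauss
# rule built by collapsing a 4x4 tensor Gauss-Legendre rule from the unit
# square onto a triangle (exact for polynomials well beyond the cubic
# integrands at stake), evaluating the basis functions from their
# barycentric definition. Deliberately shares no code with the assembly
# path in R/fem.R.

gauss_legendre_01 <- function(n = 4) {
  # nodes/weights on [0,1] from the Golub-Welsch tridiagonal for Legendre
  j <- seq_len(n - 1)
  b <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(j, j + 1)] <- b; J[cbind(j + 1, j)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(x = (e$values + 1) / 2, w = 2 * e$vectors[1, ]^2 / 2)
}

# 16-point rule on the triangle with vertices V (3 x 2): points + weights
triangle_rule16 <- function(V) {
  gl <- gauss_legendre_01(4)
  a <- rep(gl$x, each = 4); b <- rep(gl$x, times = 4)
  wa <- rep(gl$w, each = 4); wb <- rep(gl$w, times = 4)
  # collapse: (a, b) -> barycentric (1-a, a*(1-b), a*b), jacobian a
  l1 <- 1 - a; l2 <- a * (1 - b); l3 <- a * b
  x <- l1 * V[1, 1] + l2 * V[2, 1] + l3 * V[3, 1]
  y <- l1 * V[1, 2] + l2 * V[2, 2] + l3 * V[3, 2]
  area2 <- abs((V[2, 1] - V[1, 1]) * (V[3, 2] - V[1, 2]) -
               (V[3, 1] - V[1, 1]) * (V[2, 2] - V[1, 2]))
  list(x = x, y = y, w = wa * wb * a * area2)
}

# barycentric coordinates of points (x, y) in triangle V, plus gradients
oracle_bary <- function(V, x, y) {
  Tm <- rbind(c(V[1, 1], V[2, 1], V[3, 1]),
              c(V[1, 2], V[2, 2], V[3, 2]),
              c(1, 1, 1))
  lam <- solve(Tm, rbind(x, y, 1))  # 3 x npts
  grad <- solve(Tm)[, 1:2]          # 3 x 2: rows = d(lambda_a)/d(x,y)
  list(lam = lam, grad = grad)
}

# brute-force global assemblies by summing per-triangle 16-point quadrature
oracle_assemble <- function(mesh, what, nu = 1, b = c(0, 0), u = NULL,
                            gamma = NULL, f = 0) {
  n <- nrow(mesh$nodes)
  out <- if (what == "load") numeric(n) else matrix(0, n, n)
  for (k in seq_len(nrow(mesh$triangles))) {
    idx <- mesh$triangles[k, ]
    V <- mesh$nodes[idx, , drop = FALSE]
    q <- triangle_rule16(V)
    bc <- oracle_bary(V, q$x, q$y)
    cen <- colMeans(V)
    for (a in 1:3) for (bb in 1:3) {
      if (what == "mass") {
        out[idx[a], idx[bb]] <- out[idx[a], idx[bb]] +
          sum(q$w * bc$lam[a, ] * bc$lam[bb, ])
      } else if (what == "stiffness") {
        nuv <- if (is.function(nu)) nu(matrix(cen, 1), 0) else nu
        out[idx[a], idx[bb]] <- out[idx[a], idx[bb]] +
          sum(q$w) * nuv * sum(bc$grad[a, ] * bc$grad[bb, ])
      } else if (what == "transport") {
        bv <- if (is.function(b)) as.numeric(b(matrix(cen, 1), 0)) else b
        out[idx[a], idx[bb]] <- out[idx[a], idx[bb]] +
          sum(q$w * bc$lam[a, ]) * sum(bv * bc$grad[bb, ])
      }
    }
    if (what == "load") {
      uq <- colSums(bc$lam * u[idx])
      gq <- colSums(bc$lam * gamma[idx])
      fq <- if (length(f) == 1) rep(f, length(uq)) else colSums(bc$lam * f[idx])
      for (a in 1:3) {
        out[idx[a]] <- out[idx[a]] +
          sum(q$w * ((gq - uq) * uq + fq) * bc$lam[a, ])
      }
    }
  }
  out
}
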