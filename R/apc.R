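# Data-driven arbitrary polynomial chaos: orthonormal polynomials and
# Gaussian quadrature built from raw statistical moments of arbitrary
# (sample- or histogram-given) input distributions, combined across
# dimensions with Smolyak's rule.

#' Raw sample moments
#'
#' `mu_k = mean(x^k)` for `k = 0 .. upto`.
#'
#' @param samples numeric vector
#' @param upto highest moment order
#' @return numeric vector of length `upto + 1` (`mu_0 = 1` first)
#' @export
raw_moments <- function(samples, upto) {
  if (upto >= 1 && length(unique(samples)) < 2)
    stop("degeneracy error: all samples identical; moments above order 0 ",
         "carry no information for an orthogonal family")
  vapply(0:upto, function(k) mean(samples^k), 0)
}

#' Uncertain model input
#'
#' Wraps one uncertain parameter given either as raw samples or as a
#' histogram (bin edges + counts). Moments are the empirical raw moments of
#' the samples, or the count-weighted moments of the bin midpoints.
#'
#' @param name identifier (e.g. `"nu"`, `"alpha"`)
#' @param samples numeric vector of observed/synthetic values
#' @param histogram alternative to `samples`: list with `breaks` (length
#'   nb + 1) and `counts` (length nb)
#' @param moments alternative to both: the exact raw moments
#'   `mu_0, mu_1, ...` (with `mu_0 = 1`); such an input supports quadrature
#'   and basis construction but not bootstrap sampling
#' @return object of class `random_input`
#' @export
random_input <- function(name, samples = NULL, histogram = NULL,
                         moments = NULL) {
  if (is.null(samples) && is.null(histogram) && is.null(moments))
    stop("provide samples, a histogram, or moments")
  if (!is.null(moments) && abs(moments[1] - 1) > 1e-12)
    stop("mu_0 must equal 1")
  if (!is.null(histogram)) {
    nb <- length(histogram$counts)
    if (length(histogram$breaks) != nb + 1)
      stop("histogram breaks must have length counts + 1")
    mids <- (histogram$breaks[-1] + histogram$breaks[-(nb + 1)]) / 2
    wts <- histogram$counts / sum(histogram$counts)
  } else {
    mids <- NULL; wts <- NULL
  }
  structure(list(name = name, samples = samples,
                 hist_mids = mids, hist_weights = wts, moments = moments),
            class = "random_input")
}

#' @export
print.random_input <- function(x, ...) {
  src <- if (!is.null(x$samples))
    sprintf("%d samples", length(x$samples))
  else sprintf("histogram with %d bins", length(x$hist_mids))
  cat(sprintf("<random_input> %s: %s, mean %.6g\n", x$name, src,
              input_moments(x, 1)[2]))
  invisible(x)
}

#' Moments of a random input
#' @param input a [random_input()]
#' @param upto highest order
#' @return raw moments `mu_0 .. mu_upto`
#' @export
input_moments <- function(input, upto) {
  if (!is.null(input$moments)) {
    if (length(input$moments) < upto + 1)
      stop("input '", input$name, "' stores moments only up to order ",
           length(input$moments) - 1)
    return(input$moments[1:(upto + 1)])
  }
  if (!is.null(input$samples))
    return(vapply(0:upto, function(k) mean(input$samples^k), 0))
  vapply(0:upto, function(k) sum(input$hist_weights * input$hist_mids^k), 0)
}

# Bootstrap-resample n values from the stored data.
input_sample <- function(input, n) {
  if (!is.null(input$samples)) {
    if (length(input$samples) == 0) stop("data error: empty sample pool")
    return(sample(input$samples, n, replace = TRUE))
  }
  if (length(input$hist_mids) == 0)
    stop("data error: input '", input$name,
         "' has no samples or histogram to resample")
  sample(input$hist_mids, n, replace = TRUE, prob = input$hist_weights)
}

# Three-term recurrence of the moment-orthonormal polynomials via the
# Cholesky factor of the Hankel moment matrix (Mysovskikh):
#   p_0 = 1,  b_1 p_1 = x - a_1,
#   b_{j+1} p_{j+1} = (x - a_{j+1}) p_j - b_j p_{j-1}.
moment_recurrence <- function(mu, m) {
  # degenerate (zero-variance) input: all mass at the mean; higher-degree
  # orthonormal polynomials do not exist (b_j = 0 signals this downstream)
  if (mu[3] - mu[2]^2 <= 1e-14 * max(1, mu[2]^2))
    return(list(a = rep(mu[2], m), b = rep(0, m), degenerate = TRUE))
  H <- outer(1:(m + 1), 1:(m + 1), function(i, j) mu[i + j - 1])
  R <- tryCatch(chol(H), error = function(e)
    stop("conditioning error: Hankel moment matrix of order ", m,
         " is numerically singular; use fewer moments (",
         conditionMessage(e), ")"))
  a <- numeric(m); b <- numeric(m)
  for (j in 1:m) {
    a[j] <- R[j, j + 1] / R[j, j] - if (j > 1) R[j - 1, j] / R[j - 1, j - 1] else 0
    b[j] <- R[j + 1, j + 1] / R[j, j]
  }
  list(a = a, b = b)
}

# Evaluate orthonormal polynomials p_0..p_deg at x: matrix length(x) x (deg+1)
eval_orthopoly <- function(recur, deg, x) {
  out <- matrix(0, length(x), deg + 1)
  out[, 1] <- 1
  if (deg >= 1)
    out[, 2] <- if (recur$b[1] == 0) 0 else (x - recur$a[1]) / recur$b[1]
  if (deg >= 2) for (j in 2:deg) {
    out[, j + 1] <- if (recur$b[j] == 0) 0 else
      ((x - recur$a[j]) * out[, j] -
       recur$b[j - 1] * out[, j - 1]) / recur$b[j]
  }
  out
}

#' Moment-based Gaussian quadrature rule
#'
#' Builds the `m`-point Gaussian rule of an arbitrary input distribution
#' from its raw moments: the three-term recurrence of the
#' moment-orthonormal polynomials is extracted from the Cholesky factor of
#' the Hankel moment matrix, and nodes/weights come from the spectral
#' decomposition of the associated symmetric tridiagonal (Jacobi) matrix.
#' The rule integrates monomials `x^0 .. x^(2m-1)` to the input's moments.
#'
#' @param input a [random_input()]
#' @param m number of quadrature nodes (order)
#' @return object of class `quadrature_rule`: `nodes`, `weights`, `order`,
#'   `recurrence`
#' @export
quadrature_from_moments <- function(input, m) {
  mu <- input_moments(input, 2 * m)
  rec <- moment_recurrence(mu, m)
  if (isTRUE(rec$degenerate)) {
    return(structure(list(nodes = rep(mu[2], m),
                          weights = c(1, rep(0, m - 1)),
                          order = m, recurrence = rec),
                     class = "quadrature_rule"))
  }
  if (m == 1) {
    nodes <- rec$a[1]; weights <- 1
  } else {
    J <- diag(rec$a, m, m)
    for (j in 1:(m - 1)) J[j, j + 1] <- J[j + 1, j] <- rec$b[j]
    e <- eigen(J, symmetric = TRUE)
    ord <- order(e$values)
    nodes <- e$values[ord]
    weights <- (e$vectors[1, ord])^2
  }
  structure(list(nodes = as.numeric(nodes), weights = as.numeric(weights),
                 order = m, recurrence = rec),
            class = "quadrature_rule")
}

#' @export
print.quadrature_rule <- function(x, ...) {
  cat(sprintf("<quadrature_rule> order %d\n  nodes:   %s\n  weights: %s\n",
              x$order, paste(signif(x$nodes, 6), collapse = " "),
              paste(signif(x$weights, 6), collapse = " ")))
  invisible(x)
}

#' Smolyak sparse quadrature grid
#'
#' Combines per-dimension families of moment-based Gaussian rules with the
#' standard Smolyak combination formula at level `l` in `d` dimensions:
#' sum over multi-indices `l+1 <= |i| <= l+d` of
#' `(-1)^(l+d-|i|) C(d-1, l+d-|i|)` times the tensor product of the 1-D
#' rules `U^{i_k}` (the rule of size `i_k`). Duplicate points are merged
#' with summed weights; weights may be negative but always sum to 1.
#'
#' @param inputs list of [random_input()] objects (one per dimension)
#' @param level Smolyak level `l >= 0`
#' @return object of class `sparse_grid`: `points` (P x d, columns named by
#'   input), `weights`, `level`, `d`, `rules` (per-dimension rule families)
#' @export
smolyak_grid <- function(inputs, level = 1L) {
  d <- length(inputs)
  if (d < 1) stop("need at least one input")
  max_order <- level + 1L
  rules <- lapply(inputs, function(inp)
    lapply(seq_len(max_order), function(i) quadrature_from_moments(inp, i)))
  combos <- multi_indices_between(d, level + 1L, level + d)
  pts <- list(); wts <- list()
  for (r in seq_len(nrow(combos))) {
    i_vec <- combos[r, ]
    coef <- (-1)^(level + d - sum(i_vec)) *
            choose(d - 1, level + d - sum(i_vec))
    nodes_k <- lapply(seq_len(d), function(k) rules[[k]][[i_vec[k]]]$nodes)
    wts_k <- lapply(seq_len(d), function(k) rules[[k]][[i_vec[k]]]$weights)
    P <- as.matrix(expand.grid(nodes_k))
    W <- apply(as.matrix(expand.grid(wts_k)), 1, prod) * coef
    pts[[r]] <- P; wts[[r]] <- W
  }
  P <- do.call(rbind, pts); W <- unlist(wts)
  # merge duplicates (relative key per dimension)
  scale <- apply(abs(P), 2, max)
  scale[scale == 0] <- 1
  key <- apply(round(sweep(P, 2, scale, "/"), 9), 1, paste, collapse = "|")
  uk <- !duplicated(key)
  merged_w <- as.numeric(rowsum(W, key, reorder = FALSE)[, 1])
  mp <- P[uk, , drop = FALSE]
  colnames(mp) <- vapply(inputs, `[[`, "", "name")
  structure(list(points = mp, weights = merged_w, level = level, d = d,
                 rules = rules,
                 input_names = colnames(mp)),
            class = "sparse_grid")
}

# rowsum(key groups) keeps first-appearance order with reorder = FALSE,
# matching !duplicated(key) row selection.

multi_indices_between <- function(d, lo, hi) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(hi)), d)))
  s <- rowSums(grid)
  grid[s >= lo & s <= hi, , drop = FALSE]
}

#' @export
print.sparse_grid <- function(x, ...) {
  cat(sprintf("<sparse_grid> level %d, %d dims, %d points (weights sum %.3g)\n",
              x$level, x$d, nrow(x$points), sum(x$weights)))
  invisible(x)
}

#' Multivariate orthonormal chaos basis
#'
#' Tensor products of the per-input moment-orthonormal polynomials with
#' total degree at most `level`. `psi_1` is the constant 1.
#'
#' @param inputs list of [random_input()] objects
#' @param level maximum total degree
#' @return object of class `pce_basis` with `indices` (K x d multi-index
#'   matrix) and per-dimension recurrences
#' @export
pce_basis <- function(inputs, level = 1L) {
  d <- length(inputs)
  recs <- lapply(inputs, function(inp)
    moment_recurrence(input_moments(inp, 2 * (level + 1)), level + 1))
  grid <- as.matrix(expand.grid(rep(list(0:level), d)))
  idx <- grid[rowSums(grid) <= level, , drop = FALSE]
  idx <- idx[order(rowSums(idx), apply(idx, 1, paste, collapse = "")), ,
             drop = FALSE]
  structure(list(indices = idx, recurrences = recs, d = d, level = level,
                 input_names = vapply(inputs, `[[`, "", "name")),
            class = "pce_basis")
}

#' Evaluate the chaos basis at points
#' @param basis a [pce_basis()]
#' @param X n x d matrix of input values
#' @return n x K matrix of basis values
#' @export
eval_basis <- function(basis, X) {
  if (is.null(dim(X))) X <- matrix(X, ncol = basis$d)
  K <- nrow(basis$indices)
  polys <- lapply(seq_len(basis$d), function(k)
    eval_orthopoly(basis$recurrences[[k]], basis$level, X[, k]))
  out <- matrix(1, nrow(X), K)
  for (j in seq_len(K)) for (k in seq_len(basis$d)) {
    deg <- basis$indices[j, k]
    if (deg > 0) out[, j] <- out[, j] * polys[[k]][, deg + 1]
  }
  out
}

#' Pseudo-spectral projection onto the chaos basis
#'
#' Computes the expansion coefficients
#' `alpha_k = sum_i w(eta_i) psi_k(eta_i) theta_i / sum_i psi_k(eta_i)^2 theta_i`
#' from model evaluations at the sparse-grid points. Evaluations may be a
#' vector (scalar output) or a matrix with one row per grid point (whole
#' nodal fields; the projection is applied column-wise).
#'
#' @param evals length-P vector or P x Q matrix of model outputs
#' @param grid a [smolyak_grid()]
#' @param basis a [pce_basis()]
#' @return object of class `pc_expansion` with `coefficients` (K x Q),
#'   `basis`, `grid`
#' @export
pce_project <- function(evals, grid, basis) {
  if (is.null(dim(evals))) evals <- matrix(evals, ncol = 1)
  if (nrow(evals) != nrow(grid$points))
    stop(sprintf("dimension error: %d evaluations for %d grid points",
                 nrow(evals), nrow(grid$points)))
  Psi <- eval_basis(basis, grid$points)
  theta <- grid$weights
  norms <- colSums(Psi^2 * theta)
  # basis functions involving a degenerate (zero-variance) dimension have
  # zero discrete norm; their coefficients are defined as 0
  safe <- ifelse(abs(norms) < 1e-300, 1, norms)
  coef <- crossprod(Psi * theta, evals) / safe
  coef[abs(norms) < 1e-300, ] <- 0
  structure(list(coefficients = coef, basis = basis, grid = grid),
            class = "pc_expansion")
}

#' Evaluate a chaos surrogate
#' @param expansion a [pce_project()] result
#' @param X n x d matrix of input values
#' @return n x Q matrix of surrogate outputs
#' @export
pce_eval <- function(expansion, X) {
  eval_basis(expansion$basis, X) %*% expansion$coefficients
}

#' Surrogate mean (the coefficient of the constant basis function)
#' @param expansion a [pce_project()] result
#' @return length-Q vector
#' @export
pce_mean <- function(expansion) {
  as.numeric(expansion$coefficients[1, ])
}

#' Surrogate standard deviation under the input measure
#'
#' For an orthonormal basis the surrogate variance is the sum of squared
#' non-constant coefficients.
#' @param expansion a [pce_project()] result
#' @return length-Q vector (>= 0)
#' @export
pce_sd <- function(expansion) {
  co <- expansion$coefficients
  if (nrow(co) == 1) return(rep(0, ncol(co)))
  sqrt(pmax(colSums(co[-1, , drop = FALSE]^2), 0))
}

#' @export
print.pc_expansion <- function(x, ...) {
  cat(sprintf("<pc_expansion> %d basis functions x %d outputs (level %d, %d dims)\n",
              nrow(x$coefficients), ncol(x$coefficients),
              x$basis$level, x$basis$d))
  invisible(x)
}

#' Synthetic input histograms from named parametric families
#'
#' Seeded sampling from `"normal"` or `"uniform"` families, returning
#' [random_input()] objects carrying the samples. Defaults mirror the
#' reference uncertainty scenario: diffusion `nu ~ N(5e-4, 1.2e-4)` and
#' carrying-capacity scale `alpha ~ U(0, 2)`.
#'
#' @param spec named list; each element a list with `family` (`"normal"`:
#'   `mean`, `sd`; `"uniform"`: `min`, `max`)
#' @param n samples per input (>= 100)
#' @param seed integer seed
#' @return named list of [random_input()] objects
#' @export
synth_histograms <- function(spec = reference_uq_inputs(), n = 10000L,
                             seed = 1L) {
  if (n < 100) stop("n must be at least 100")
  with_preserved_seed(seed, {
    out <- lapply(names(spec), function(nm) {
      s <- spec[[nm]]
      x <- switch(s$family,
        normal = stats::rnorm(n, s$mean, s$sd),
        uniform = stats::runif(n, s$min, s$max),
        stop("configuration error: unknown distribution family '",
             s$family, "'"))
      random_input(nm, samples = x)
    })
    stats::setNames(out, names(spec))
  })
}

#' Reference uncertain-parameter specification
#'
#' The two uncertain inputs of the reference scenario: the diffusion
#' coefficient `nu ~ N(5e-4, 1.2e-4)` (deg^2/yr) and the carrying-capacity
#' scale `alpha ~ U(0, 2)`.
#' @return named list usable as `spec` in [synth_histograms()]
#' @export
reference_uq_inputs <- function() {
  list(nu = list(family = "normal", mean = 5e-4, sd = 1.2e-4),
       alpha = list(family = "uniform", min = 0, max = 2))
}
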