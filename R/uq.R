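# Propagation of parametric uncertainty through the dispersal model:
# evaluate the deterministic model at the Smolyak points, project onto the
# chaos basis, then Monte-Carlo the cheap surrogate (bootstrap resampling
# of the stored input samples, independent across dimensions) for output
# PDFs and arrival-time distributions. Mean and standard-deviation fields
# come directly from the orthonormal expansion coefficients (the exact
# surrogate moments under the input measure).

#' Monte Carlo on a chaos surrogate
#'
#' Draws `n_samples` input vectors by bootstrap-resampling the stored input
#' samples (independently per dimension), evaluates the surrogate, and
#' returns moments and the raw output samples. Deterministic for a fixed
#' seed.
#'
#' @param expansion a [pce_project()] result
#' @param inputs the list of [random_input()] objects the expansion was
#'   built from
#' @param n_samples number of Monte Carlo draws (>= 1000)
#' @param seed integer seed
#' @param keep_samples return the raw output sample matrix (set `FALSE` for
#'   large output dimensions)
#' @return object of class `surrogate_mc`: `mean`, `sd` (length Q),
#'   `samples` (n x Q or `NULL`), `inputs_drawn` (n x d)
#' @export
surrogate_mc <- function(expansion, inputs, n_samples = 1e5, seed = 1L,
                         keep_samples = TRUE) {
  if (n_samples < 1000) stop("n_samples must be at least 1000")
  X <- with_preserved_seed(seed, {
    do.call(cbind, lapply(inputs, input_sample, n = n_samples))
  })
  vals <- pce_eval(expansion, X)
  structure(list(mean = colMeans(vals),
                 sd = apply(vals, 2, stats::sd),
                 samples = if (keep_samples) vals else NULL,
                 inputs_drawn = X),
            class = "surrogate_mc")
}

# First upward crossing of threshold for each row of a series matrix
# (rows = realizations, cols = time points), linear in time; Inf if never.
crossing_times <- function(series, times, threshold) {
  n <- nrow(series); m <- ncol(series)
  out <- rep(Inf, n)
  done <- series[, 1] >= threshold
  out[done] <- times[1]
  for (j in 2:m) {
    hit <- !done & series[, j] >= threshold
    if (any(hit)) {
      u0 <- series[hit, j - 1]; u1 <- series[hit, j]
      frac <- (threshold - u0) / (u1 - u0)
      frac[!is.finite(frac)] <- 0
      out[hit] <- times[j - 1] + pmin(pmax(frac, 0), 1) * (times[j] - times[j - 1])
      done <- done | hit
    }
    if (all(done)) break
  }
  out
}

#' Full uncertainty-quantification run
#'
#' Builds per-input quadratures and the level-`level` Smolyak grid, runs one
#' deterministic simulation per grid point (5 runs for two inputs at level
#' 1), projects every saved snapshot and probe series onto the chaos basis,
#' and Monte-Carlos the surrogate probe series for density PDFs and
#' arrival-time distributions.
#'
#' @param mesh a [tri_mesh()] with elevation attached
#' @param inputs named list of [random_input()] objects; names must match
#'   the arguments of `coef_fn`
#' @param coef_fn function `(theta)` (named numeric vector, one entry per
#'   input) returning the [coefficient_set()] for those parameter values;
#'   default: the elevation scenario with `theta["nu"]`, `theta["alpha"]`
#' @param u0 initial nodal vector
#' @param dt,T_end,threshold,probes,stride,solver forwarded to
#'   [run_simulation()]
#' @param level Smolyak level
#' @param n_mc surrogate Monte Carlo draws
#' @param seed seed for the surrogate Monte Carlo
#' @param mass mass-matrix treatment, see [run_simulation()]
#' @return object of class `uq_result`: `times`, `mean`/`sd` (N x n_snap
#'   field moments), `probe_times`, `probe_mean`/`probe_sd`,
#'   `arrival_samples` (n_mc x P), `density_samples_final` (n_mc x P),
#'   `n_runs`, `grid`, `field_expansion`, `probe_expansion`
#' @export
run_uq <- function(mesh, inputs, coef_fn = NULL, u0, dt = 1 / 120, T_end,
                   threshold = 1, probes = NULL, stride = 10L, level = 1L,
                   n_mc = 1e5, seed = 1L, solver = "direct",
                   mass = "consistent") {
  if (is.null(coef_fn))
    coef_fn <- function(theta)
      elevation_scenario_coefficients(mesh, alpha = theta[["alpha"]],
                                      nu0 = theta[["nu"]])
  grid <- smolyak_grid(inputs, level)
  basis <- pce_basis(inputs, level)
  P <- nrow(grid$points)
  runs <- vector("list", P)
  for (i in seq_len(P)) {
    theta <- stats::setNames(as.numeric(grid$points[i, ]), grid$input_names)
    runs[[i]] <- run_simulation(mesh, coef_fn(theta), u0, dt = dt,
                                T_end = T_end, threshold = threshold,
                                probes = probes, stride = stride,
                                solver = solver, mass = mass)
  }
  n_snap <- length(runs[[1]]$times)
  n_nodes <- nrow(runs[[1]]$snapshots)
  field_evals <- do.call(rbind, lapply(runs, function(r)
    as.numeric(r$snapshots)))
  field_exp <- pce_project(field_evals, grid, basis)
  mean_field <- matrix(pce_mean(field_exp), n_nodes, n_snap)
  sd_field <- matrix(pce_sd(field_exp), n_nodes, n_snap)

  probe_exp <- NULL
  probe_mean <- probe_sd <- NULL
  arrival_samples <- density_final <- NULL
  probe_times <- NULL
  if (!is.null(probes)) {
    probe_times <- runs[[1]]$probe_times
    pn <- colnames(runs[[1]]$probe_series)
    probe_evals <- do.call(rbind, lapply(runs, function(r)
      as.numeric(r$probe_series)))
    probe_exp <- pce_project(probe_evals, grid, basis)
    np <- length(pn); nt <- length(probe_times)
    probe_mean <- matrix(pce_mean(probe_exp), nt, np, dimnames = list(NULL, pn))
    probe_sd <- matrix(pce_sd(probe_exp), nt, np, dimnames = list(NULL, pn))
    # chunked surrogate MC over realizations: per-realization probe series
    # -> arrival time and final density
    X <- with_preserved_seed(seed, {
      do.call(cbind, lapply(inputs, input_sample, n = n_mc))
    })
    arrival_samples <- matrix(NA_real_, n_mc, np, dimnames = list(NULL, pn))
    density_final <- matrix(NA_real_, n_mc, np, dimnames = list(NULL, pn))
    chunk <- max(1L, as.integer(2e6 / (nt * np)))
    i0 <- 1L
    while (i0 <= n_mc) {
      i1 <- min(i0 + chunk - 1L, n_mc)
      vals <- pce_eval(probe_exp, X[i0:i1, , drop = FALSE]) # rows x (nt*np)
      for (p in seq_len(np)) {
        cols <- ((p - 1) * nt + 1):(p * nt)
        arrival_samples[i0:i1, p] <-
          crossing_times(vals[, cols, drop = FALSE], probe_times, threshold)
        density_final[i0:i1, p] <- vals[, cols[nt]]
      }
      i0 <- i1 + 1L
    }
  }
  structure(
    list(times = runs[[1]]$times, mean = mean_field, sd = sd_field,
         probe_times = probe_times, probe_mean = probe_mean,
         probe_sd = probe_sd, arrival_samples = arrival_samples,
         density_samples_final = density_final,
         n_runs = P, grid = grid, field_expansion = field_exp,
         probe_expansion = probe_exp, threshold = threshold, seed = seed),
    class = "uq_result")
}

#' @export
print.uq_result <- function(x, ...) {
  cat(sprintf(
    "<uq_result> %d model runs on a level-%d grid; %d nodes x %d snapshots\n",
    x$n_runs, x$grid$level, nrow(x$mean), ncol(x$mean)))
  if (!is.null(x$probe_mean))
    cat(sprintf("  probes: %s\n", paste(colnames(x$probe_mean),
                                        collapse = ", ")))
  invisible(x)
}

#' Normalized output PDF from a UQ result
#'
#' Histogram density (integrating to 1) of a probe's arrival time or final
#' density over the surrogate Monte Carlo samples. Non-finite arrival
#' samples (realizations that never reach the threshold) are excluded and
#' their fraction reported.
#'
#' @param uq a [run_uq()] result
#' @param probe probe name or index
#' @param what `"arrival"` or `"density"`
#' @param breaks passed to [hist()]
#' @return list with `mids`, `density`, `breaks`, `prop_finite`
#' @export
probe_pdf <- function(uq, probe, what = c("arrival", "density"),
                      breaks = 50) {
  what <- match.arg(what)
  x <- switch(what, arrival = uq$arrival_samples[, probe],
              density = uq$density_samples_final[, probe])
  ok <- is.finite(x)
  h <- graphics::hist(x[ok], breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, breaks = h$breaks,
       prop_finite = mean(ok))
}
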