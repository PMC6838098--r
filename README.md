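# invadefem

Finite-element simulation of invasive-species spread on real terrain, with
data-driven polynomial-chaos uncertainty quantification.

## What it is for

Environmental managers planning a response to a biological invasion need
two things a point forecast cannot give: *where and when* the species will
arrive, on the actual geography of the region, and *how confident* those
arrival maps are given poorly known species parameters. `invadefem`
addresses both:

* a deterministic core that solves a Fisher–KPP-type
  advection–diffusion–reaction equation for the population density
  $u(\vec x,t)$,

  $$\partial_t u - \nabla\!\cdot(\nu\nabla u) + \vec b\cdot\nabla u +
  u(u-\gamma) = f,$$

  with P1 finite elements on geography-aware triangular meshes (elevation
  from SRTM HGT tiles or a synthetic generator; gradient-driven red–green
  refinement; zero-flux boundary on a buffered domain) and semi-implicit
  IMEX time stepping. Elevation enters through the carrying capacity
  $\gamma = \alpha\,(10 - z/100)$: maximal at sea level, zero at 1000 m,
  hostile above. Outputs: density snapshots, per-node arrival-time maps
  (first crossing of $u = 1$), probe time series, and front speeds, which
  in homogeneous terrain converge to the classical value
  $c = 2\sqrt{\nu\gamma}$;

* an arbitrary polynomial chaos (aPC) layer that takes the uncertain
  inputs as **data** (samples or histograms, e.g. $\nu \sim N(5\times
  10^{-4}, 1.2\times10^{-4})$ deg²/yr and $\alpha \sim U(0,2)$), builds
  moment-based Gaussian quadratures and orthonormal polynomials, combines
  them on a Smolyak sparse grid (5 model runs for two inputs at level 1),
  and Monte-Carlos the resulting surrogate for mean/σ fields, probe
  density PDFs and arrival-time distributions.

## Worked example

The bundled demo builds a synthetic landscape with an east–west mountain
ridge (1500 m crest — uninhabitable above 1000 m) interrupted by one
north–south valley, and releases a colony north-east of the ridge:

```r
library(invadefem)

sc  <- ridge_demo_scenario()
sc$mesh
#> <tri_mesh> 11485 nodes, 22616 triangles, area 1.96 deg^2, with elevation

res <- run_simulation(sc$mesh, sc$coeffs, sc$u0, dt = sc$dt,
                      T_end = sc$T_end, threshold = sc$threshold,
                      probes = sc$probes, mass = sc$mass)
res
#> <simulation_result> 11485 nodes, 169 snapshots to t = 14 yr (dt = 0.008333)
#>   invaded nodes (u >= 1): 10243 of 11485

sapply(colnames(res$probe_series), function(p) {
  i <- which(res$probe_series[, p] >= 1)[1]
  round(res$probe_times[i], 2)
})
#> north   gap south
#>  1.19  4.28  5.79
```

The arrival order tells the ecological story: the northern probe is
reached within ~1.2 years, the valley gap after ~4.3 years (the ridge
blocks the direct southward path and deflects the front west), and the
southern probe only after ~5.8 years, once the species has spilled
through the valley. Terrain above 1000 m stays uninvaded (`Inf` in
`res$arrival_time`).

On a homogeneous fine strip the measured front speed validates the solver
against theory — `front_speed()` returns 0.137 deg/yr against
$2\sqrt{\nu\gamma} = 0.1414$ deg/yr (≈ 3%).

The moment-based quadrature of the uncertain diffusion input lands on the
Gauss–Hermite points $\mu \pm \sigma$:

```r
inputs <- synth_histograms(reference_uq_inputs(), n = 10000, seed = 1)
quadrature_from_moments(inputs$nu, 2)
#> <quadrature_rule> order 2
#>   nodes:   0.000376305 0.000619275
#>   weights: 0.494131 0.505869

uq <- run_uq(sc$mesh, inputs, u0 = sc$u0, dt = sc$dt, T_end = sc$T_end,
             probes = sc$probes, level = 1, mass = sc$mass)  # 5 model runs
```

`uq$mean` / `uq$sd` hold per-node, per-snapshot surrogate moments;
`probe_pdf(uq, "south", "arrival")` gives the normalized arrival-time
distribution at a probe.

A command-line wrapper over the same functions lives in
`inst/cli/invadefem.R` (`mesh`, `simulate`, `uq` subcommands, YAML/JSON
configs; see `inst/extdata/ridge_demo.yaml`).

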