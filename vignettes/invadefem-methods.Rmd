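---
title: "Modelling invasive-species spread on real terrain: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling invasive-species spread on real terrain: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invadefem)
```

## The model

`invadefem` simulates the spread of an invasive population as a
Fisher–KPP-type advection–diffusion–reaction equation for the density
$u(\vec x, t)$ on a two-dimensional geographic domain $\Omega$ (coordinates
in degrees, longitude = $x$, latitude = $y$):

$$
\partial_t u \;-\; \nabla\!\cdot(\nu(\vec x,t)\nabla u)
\;+\; \vec b(\vec x,t)\cdot\nabla u \;+\; u\,(u - \gamma(\vec x,t)) \;=\;
f(\vec x,t),
$$

with homogeneous Neumann (zero-flux) boundary conditions. The diffusion
coefficient $\nu$ (deg$^2$ yr$^{-1}$) encodes how readily individuals
disperse; the carrying capacity $\gamma$ is the equilibrium density a
location can sustain; $\vec b$ models directed transport (rivers); $f$ is
an external source. In homogeneous terrain with constant $\nu$ and
$\gamma > 0$ the solutions are travelling invasion fronts with minimal
speed $c = 2\sqrt{\nu\gamma}$ — the classical benchmark we use to validate
the solver.

Geography enters through the coefficients. The reference scenario ties the
carrying capacity to elevation,

$$
\gamma(\vec x) = \alpha\,\bigl(10 - z(\vec x)/100\bigr),
$$

so that (at $\alpha = 1$) the species enjoys $\gamma = 10$ density units at
sea level, loses one unit per 100 m of altitude, and cannot persist above
1000 m. We deliberately do **not** clamp $\gamma$ at zero: above the
1000 m line $\gamma < 0$ makes the reaction term $u(\gamma - u)u$ strictly
damping, so high terrain is actively hostile rather than merely neutral.
Additional heterogeneities (lakes, inhospitable patches) are masks that
multiply $\gamma$ and $\nu$ on node sets; lakes force $\gamma = 0$.
The dimensionless scale $\alpha$ exists so that the uncertainty analysis
can treat "how hospitable is the landscape overall" as a random input.

Time is measured in years throughout; configuration values given in months
(the natural unit for the time step) are converted on input. The default
step is 0.1 months $= 1/120$ yr.

## Terrain

Elevation comes either from SRTM HGT tiles (raw big-endian 16-bit
integers, 1201×1201 or 3601×3601 per 1°×1° tile, void sentinel −32768,
rows stored north-first on disk and re-ordered south-first in memory so
indices increase with latitude), or from a synthetic generator: a Gaussian
ridge of configurable amplitude and width along a parallel, optionally
interrupted by a Gaussian valley notch, plus seeded noise. The generator
exists so that every test and the bundled demo run without downloads; it
emulates the *one* landscape trait the model couples to — elevation with a
mountain barrier and a valley corridor. It does not emulate drainage
networks, land-cover classes, anisotropic roughness or voids, so passing
tests say nothing about those aspects of real tiles (voids are exercised
separately with hand-made grids).

Point elevations are obtained by bilinear interpolation of the four
surrounding cells; if any of the four is void the nearest non-void cell
value is used instead (voids are rare and the PDE needs a defined $z$
everywhere; the source data offers no principled fill).

## Meshing

The computational domain is the region of interest enlarged by a buffer
margin (default 0.5°) so that the zero-flux boundary cannot contaminate
the region of interest — the usual far-field trick. `generate_mesh`
triangulates rectangles with a structured right-isosceles grid and convex
polygons with a centroid fan, then iteratively applies **red–green
refinement** until no triangle's longest edge exceeds the local target
size (a constant or a size field; a smaller target applies inside the
region of interest). Red subdivision splits a triangle into four similar
children through the edge midpoints; neighbours left with one hanging
midpoint are bisected ("green"), and — the key quality rule — a green
bisection is only permitted across a triangle's *longest* edge, otherwise
the triangle is promoted to red. Green triangles touched by later passes
are likewise promoted. Consequences: the mesh stays conforming (every
interior edge shared by exactly two triangles), total area is preserved
exactly, and on rectangular domains every element remains right-isosceles
(minimum angle 45°), hence non-obtuse — a property the solver exploits
(below). A further pass (`gradient_refine`) splits every triangle whose
P1 elevation-gradient magnitude exceeds a threshold (default
2000 m/deg), concentrating resolution on ridge flanks and valley sides;
elevations are re-interpolated after each pass.

We chose red–green refinement over re-meshing from scratch because it is
deterministic, preserves node identities across passes (convenient for
testing), and never degrades element quality below the one controlled
green level. Non-convex domains are out of scope; the geographic domains
we target are rectangles in lon/lat.

## Discretization

Space: P1 (piecewise-linear) Lagrange elements. The mass matrix uses the
exact element block $\tfrac{|T|}{12}\begin{psmallmatrix}2&1&1\\1&2&1\\1&1&2\end{psmallmatrix}$;
$\nu$ and $\vec b$ are sampled at element centroids (a one-point rule,
exact because the remaining integrands are constant or linear per
element); the cubic reaction integrand $(\gamma_h - u_h)u_h\phi_i$ uses a
4-point degree-3 triangle rule, exact for P1 data. These are the cheapest
rules that integrate their respective integrands exactly; the test suite
checks all four assemblies against an independent 16-point collapsed
Gauss oracle to $10^{-10}$.

Time: an IMEX (implicit–explicit) step — stiffness and transport
implicit, reaction explicit:

$$
(M + \Delta t\,A + \Delta t\,B)\,u^{n+1} = M u^n + \Delta t\,F(u^n).
$$

The system matrix is constant whenever the coefficients are
time-independent, so it is factorized **once** (sparse Cholesky when
$\vec b \equiv 0$ and the matrix is symmetric positive definite, sparse LU
otherwise) and each step costs two triangular solves at machine-precision
residuals, comfortably inside the $10^{-10}$ residual contract. A
Jacobi-preconditioned conjugate-gradient solver (`solver = "cg"`) is
available for the symmetric case and errors with the final residual if it
fails to converge; for this problem class the cached direct factorization
is both faster and simpler, which is why it is the default.

### Consistent versus lumped mass

The scheme above is first-order accurate in time. Two practical
consequences matter:

* **Accuracy.** In spatially uniform conditions the scheme reduces exactly
  to the forward-Euler logistic recurrence
  $u_{n+1} = u_n + \Delta t\,u_n(\gamma - u_n)$. At $\gamma = 10$ and
  $\Delta t = 1/120$ yr the maximum relative deviation from the closed-form
  logistic curve over $\gamma t \le 5$ is about 8.7% — the price of the
  explicit reaction at this step size. The error is first order: it drops
  below 1% by $\Delta t = 1/1200$ yr, which the suite verifies together
  with the halving-of-error-under-halving-of-dt signature.

* **Positivity.** With the consistent mass matrix, meshes that
  under-resolve the front width $\sqrt{\nu/\gamma}$ (≈ 0.007 deg for the
  reference coefficients) produce Gibbs-type undershoots below $u = 0$;
  since $u(\gamma - u)$ is unstable for $u < 0$, undershoots grow
  explosively. `run_simulation(mass = "lumped")` replaces $M$ by its
  row-sum diagonal and evaluates the reaction nodally; the step matrix
  then is an M-matrix on non-obtuse meshes (which our generator always
  produces) and the update preserves positivity at any resolution, at the
  cost of slightly more numerical front diffusion. The consistent form
  remains the default and is the right choice on fine meshes (the
  wave-speed benchmark resolves the front and measures
  $c = 2\sqrt{\nu\gamma}$ to within 3%); the bundled landscape demo runs
  on a deliberately coarse mesh and therefore uses the lumped form. The
  blow-up detector reports the offending step either way.

Arrival times are recorded per node as the first upward crossing of the
threshold (default 1 density unit), linearly interpolated between the
bracketing steps; nodes starting at or above threshold get 0 and nodes
never reached keep `Inf`. Probe series are P1-interpolated inside the
containing triangle at every step. `front_speed` fits arrival time
against distance along a transect by least squares and inverts the slope.

A known limitation worth stating: the $u = 1$ arrival threshold can creep
a few tens of metres of elevation past the $\gamma = 0$ contour where the
terrain slope is finite, because the stationary interface layer has width
$(\nu/|\partial\gamma/\partial x|)^{1/3}$ (≈ 0.02 deg here) and carries
densities of order 1 slightly into the hostile side. On arrival-time maps
this shows as a hairline rim on steep barriers; the barrier interior stays
empty.

## Uncertainty quantification

The uncertain inputs are data-given: raw samples or histograms, not named
parametric families. For each input we compute raw moments
$\mu_k = \frac1N\sum x_i^k$ (or count-weighted bin-midpoint moments), build
the three-term recurrence of the moment-orthonormal polynomials from the
Cholesky factor of the Hankel moment matrix, and obtain Gaussian
quadrature nodes/weights from the spectral decomposition of the associated
Jacobi matrix. A rule of order $m$ reproduces the input's moments up to
degree $2m-1$; the suite checks this to $10^{-8}$ and checks the
closed-form 2-point rules (uniform → Gauss–Legendre $1 \pm 1/\sqrt3$ on
$U(0,2)$; normal → Gauss–Hermite $\mu \pm \sigma$).

Per-dimension rule families combine through the standard Smolyak formula

$$
A(l{+}d, d) \;=\; \sum_{l+1 \le |i| \le l+d} (-1)^{\,l+d-|i|}
\binom{d-1}{\,l+d-|i|\,} \; \bigotimes_{k=1}^{d} U^{i_k},
$$

with duplicate points merged (weights summed; weights may be negative but
always sum to 1). With two inputs at level 1 this gives the 5-point cross:
the bivariate mean with weight −1 plus the four axis points with weight
½ each. The chaos basis is the tensor product of the per-input orthonormal
polynomials truncated at **total degree ≤ level** (the standard choice; 3
functions at level 1 in two dimensions), and the expansion coefficients
come from pseudo-spectral projection with the squared-norm denominator
$\alpha_k = \sum_i w(\eta_i)\psi_k(\eta_i)\theta_i \big/
\sum_i \psi_k(\eta_i)^2\theta_i$ — without the square the denominator of
every non-constant mode would vanish by orthogonality.

Degenerate (zero-variance) inputs are supported: their higher-degree
polynomials do not exist, so the corresponding basis functions evaluate to
zero and their coefficients are defined as 0, which makes "σ = 0 under a
variance-free input" an identity rather than a numerical accident.

`run_uq` executes one deterministic simulation per sparse-grid point
(5 runs in the reference setting) and projects every saved snapshot and
probe series component-wise. Mean and standard-deviation fields are read
directly off the orthonormal coefficients ($\mu = \alpha_0$,
$\sigma^2 = \sum_{k\ge1}\alpha_k^2$) — the exact surrogate moments under
the input measure. Output *distributions* (probe density PDFs,
arrival-time distributions) come from Monte Carlo on the surrogate:
$10^5$ draws by default, bootstrap-resampled from the stored input samples
independently per dimension, chunked so memory stays bounded, and fully
seeded. PDFs are never built from the signed quadrature weights.

Because the post-front equilibrium $u = \alpha(10 - z/100)$ is itself
random when $\alpha$ is uncertain, the σ field does **not** collapse to
zero behind the front: with $\alpha \sim U(0,2)$ the settled-territory σ
is $10\,\mathrm{sd}(\alpha) \approx 5.8$ at sea level, while the peak σ in
the unsettled transition zone reaches ≈ 9.3. Uncertainty therefore peaks
at the advancing edge and *decreases* in the wake, but only by a factor
≈ 0.6, not by an order of magnitude — an intrinsic property of a
carrying-capacity-scale uncertainty, worth keeping in mind when reading σ
maps.

## The bundled demo

`ridge_demo_scenario()` builds a synthetic landscape shaped like the
reference geography: a 1500 m east–west ridge (uninhabitable crest, since
$\gamma < 0$ above 1000 m) spanning the full domain width at latitude
0.55°, a single north–south valley gap at longitude 0.35°, and a colony
of density 10 in a 0.15° circle north-east of the ridge. Probes sit north
of the ridge, in the gap, and south of the ridge. The expected dynamics —
the ridge forces the species west until the valley lets it spill south —
is asserted in the tests via arrival-time ordering. Problem sizes were
chosen so a full demo (deterministic run plus the 5-run uncertainty
analysis with $2\times10^4$ surrogate draws in the tests) completes in
under a minute: region of interest 1.2°×1.2° with a 0.1° buffer,
background edge target 0.1°, 0.07° in the region of interest, one
gradient-refinement pass at 2500 m/deg (≈ 11,500 nodes), Δt = 1/120 yr,
horizon 14 yr, lumped mass. The initial colony density is set to the
sea-level carrying capacity (10); the model literature leaves this value
open and the front dynamics forget it quickly.

## Parameter summary

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `nu0` | 5e-4 | deg²/yr | diffusion coefficient |
| `alpha` | 1 | — | carrying-capacity scale |
| `dt` | 1/120 (0.1 months) | yr | IMEX time step |
| `threshold` | 1 | density | arrival-time crossing level |
| `buffer` | 0.5 | deg | domain enlargement beyond the roi |
| `gradient_threshold` | 2000 | m/deg | refinement trigger on elevation slope |
| `level` | 1 | — | Smolyak / chaos total-degree level |
| `n_mc` | 1e5 | — | surrogate Monte Carlo draws |
| colony amplitude | 10 | density | initial density inside the circle |

## Known limitations

* Long-distance (stochastic jump) dispersal, multi-species competition and
  seasonal coefficient models are out of scope; coefficients accept a time
  argument as a hook, but the reference scenario is autonomous.
* Domains must be rectangles or convex polygons; no tile mosaicking.
* The explicit reaction limits accuracy at the default step (first-order);
  halve `dt` if probe curves must track analytic growth within 1%.
* Level-1 chaos is linear in the inputs: strongly nonlinear responses
  (e.g. arrival times through a barrier under wide $\alpha$ ranges) are
  captured only to first order; raise `level` if the surrogate must bend.
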