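---
title: "Shape-model fitting of small-angle scattering curves: models, oracles and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-model fitting of small-angle scattering curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sansshape)
```

## The problem

Small-angle neutron (or X-ray) scattering of a dilute protein solution
measures the orientationally averaged single-particle intensity
$I(Q)$ as a function of momentum transfer $Q = 4\pi\sin\theta/\lambda$.
For a particle of known shape the intensity follows from the scattering
amplitude $F(q,\alpha)$ — the Fourier transform of the particle's excess
density at angle $\alpha$ between $\vec q$ and the symmetry axis:

$$ I(Q) \;=\; \mathrm{scale}\cdot
   \frac{\langle |F(Q,\alpha)|^2\rangle_\alpha}{\langle |F(0,\alpha)|^2\rangle_\alpha}
   \;+\; A_\mathrm{up}\, Q^{-p} \;+\; \mathrm{background}, \qquad
   \langle\cdot\rangle_\alpha = \int_0^{\pi/2}\!\cdot\,\sin\alpha\,d\alpha . $$

This package implements the two form-factor models needed to analyse the
cyanobacterial clock proteins and their reconstructed ancestors, and the
machinery around them: global fitting by particle swarm, Guinier/Porod
analysis, a seeded synthetic-data generator, and brute-force geometric
oracles that validate every model result.

## The dumbbell model (hexameric ring proteins: KaiC, anKaiC)

The double-ring KaiC hexamer is modelled as two identical coaxial
ellipsoids of revolution (polar semi-axis $a$, equatorial semi-axes
$r_{eq}$), centers a distance $d$ apart on the symmetry axis, pierced by
an axial cylindrical channel of radius $R_h$ — the hexamer pore. The
parameters, all in Angstrom:

| parameter | meaning | KaiC | anKaiC |
|---|---|---|---|
| `d` | ellipsoid center distance | 50 | 53 |
| `a` | polar semi-axis | 32.4 | 35.4 |
| `r_eq` | equatorial semi-axis ($b=c$) | 44.5 | 45.5 |
| `Rh` | axial hole radius | 16.8 | 17.4 |

Both published geometries have $2a > d$: the two ellipsoids
*interpenetrate*, as they must for a closed double-ring particle. This
is the central numerical subtlety of the model and drives the design:

* **Numeric amplitude (reference).** The body is described by its
  indicator function $\chi(r,z)$ = (inside ellipsoid 1 **or** ellipsoid
  2) **and** ($r > R_h$). Because the body is axially symmetric and
  mirror-symmetric in $z$,
  $$ F(q,\alpha) = 4\pi \int_0^{Z_{max}}\!\!\int_0^{r_{eq}}
     \chi(r,z)\, J_0(q r \sin\alpha)\, \cos(q z\cos\alpha)\, r\,dr\,dz .$$
  The overlap region is counted once and the hole removes only material
  actually inside an ellipsoid, so this amplitude is exact for any
  parameter combination.
* **Closed-form amplitude (fast approximation).** Linear superposition
  of two ellipsoid amplitudes (phase-shifted by $\pm d/2$) minus a
  cylinder amplitude of length $L_{tot} = d + 2a$. It double-counts the
  overlap and over-subtracts hole volume outside the ellipsoids; with
  the published geometries it deviates from the exact amplitude by up to
  tens of percent at intermediate $Q$. It is retained for limit checks
  (it is exact for non-overlapping bodies and coincident spheres) and
  fast exploration, and `dumbbell_intensity(method = "closed")` warns
  whenever the geometry overlaps.

### Quadrature

For each $z$ the admissible radii form the annulus
$(R_h,\,r_{max}(z)]$ with
$r_{max}(z) = r_{eq}\sqrt{1 - ((|z|-d/2)/a)^2}$. The radial integral
over each grid cell is therefore taken over the covered sub-interval
exactly in the $r^2$ measure with $J_0$ frozen at the cell midpoint,
while $z$ uses the midpoint rule. This "partial-cell" weighting is
second-order accurate and — crucially — separable:

$$ F = 4\pi\,\mathrm{rowSums}\big[(J_0\text{-matrix} \times W)\,\circ\,
   \cos\text{-matrix}\big], $$

where the Bessel and cosine matrices depend only on the $(Q,\alpha)$
set and the fixed grid, and only the small weight matrix $W$ depends on
the geometry. During a swarm fit the expensive matrices are built once
and each candidate geometry costs one weight matrix and one
matrix product, which is what makes a pure-R particle-swarm fit of the
exact amplitude practical.

Defaults: 256 × 256 cells over $[0, r_{eq}]\times[0, d/2+a]$ and 76
Gauss–Legendre orientation nodes for reference curves
(`dumbbell_intensity`); 128 × 128 cells and 24–32 nodes inside
`fit_dumbbell`, where the grid spans the upper bound box. Measured
against the reference settings, the fit-quality operator differs by at
most ~0.3% in intensity — an order of magnitude below the 3%
measurement noise it is fitted to. `dumbbell_amplitude_numeric` carries
a half-resolution self-convergence check that fails loudly on coarse
grids, and `orientational_average` verifies stability under node
doubling (both limits are also exercised by the test suite: limit
checks against the analytic sphere use a 512 × 512 grid, the converged
regime at the sphere form-factor zero).

## The polymer excluded-volume model (KaiA, anKaiA)

Flexible or loosely assembled proteins are described by the
excluded-volume polymer form factor (Benoit's self-avoiding chain) with
radius of gyration $R_g$ and Porod exponent $m = 1/\nu$:

$$ U = \frac{Q^2 R_g^2 (2\nu+1)(2\nu+2)}{6}, \qquad
   P(Q) = \frac{\gamma(1/2\nu,\,U)}{\nu\,U^{1/2\nu}}
        - \frac{\gamma(1/\nu,\,U)}{\nu\,U^{1/\nu}} , $$

with $\gamma$ the lower incomplete gamma function (computed via
`pgamma`), $P(0)=1$ and a high-$Q$ asymptote $\propto Q^{-m}$. At
$m = 2$ the expression collapses to the Debye Gaussian coil
$2(e^{-x}-1+x)/x^2$, which the tests verify pointwise below $10^{-8}$.
`rg` is held in nanometres (the convention in which solution-scattering
results are quoted) and converted internally; all $Q$ are in 1/Angstrom.

## Fitting

The objective is the plain chi-square on linear intensity,
$\sum_i ((I_i - I_{model,i})/\sigma_{I,i})^2$: reduced SANS data carry
per-point uncertainties, and fitting on the absolute-intensity scale is
what the measured curves were fitted on. Fits are invariant under a
common rescaling of $I$ and $\sigma_I$.

The optimizer is a global-best particle swarm with inertia 0.72 and
cognitive/social coefficients 1.49, velocities clamped to half the box
width, positions clipped to the box with the corresponding velocity
zeroed at the wall, and independent restarts (defaults: 50 particles,
500 iterations, 5 restarts). Every run is bit-reproducible from its
seed, the global-best trace is non-increasing by construction, and
`bounds_hit` flags report parameters that finish on a box edge — the
honest symptom of an unidentifiable or degenerate parameter, rather
than silently accepting an edge solution. Default boxes are ±50% around
the starting values. When the two ellipsoids overlap, `d` and `a` trade
off against each other to a degree; at the 3% noise level of the
recovery experiments both remain identifiable (no bound is hit and both
recover within a few percent).

When a curve carries a `sigma_q` column the model is smeared with a
per-point Gaussian resolution kernel (truncated at $\pm3\sigma_Q$,
renormalised) before the chi-square — the standard first-order account
of instrumental resolution for reduced 1-D data. Low-$Q$ cluster
scattering ("upturn") can either be fitted jointly as an additive
$A_{up} Q^{-p}$ term with $p \in [2,4]$ free, or excluded by
truncating the curve with `trim_curve` before fitting; both modes are
supported because the measured curves only characterise the upturn
qualitatively.

## Oracles

Every analytic or quadrature result is validated against machinery that
shares nothing with it:

* `sample_points` — uniform rejection sampling of the indicator inside
  the bounding cylinder (seeded, deterministic).
* `mc_volume`, `mc_rg` — Monte-Carlo volume and radius of gyration with
  standard errors ($n^{-1/2}$ convergence is itself tested).
* `debye_intensity` — the Debye pair sum
  $I(q) = N^{-2}\sum_{ij}\mathrm{sinc}(q\,r_{ij})$, exact for small
  clouds and via a fine pair-distance histogram (0.25 A bins by
  default, 0.05 A in the tests) for large ones, with a numerically
  stable sinc. The finite-$N$ self term $1/N$ can be subtracted
  (`subtract_self`) when the cloud stands in for a continuous body.

One limitation deserves emphasis. A point-cloud Debye estimator has a
Monte-Carlo noise floor of order $10^{-5}\,I(0)$ at $N = 2\times10^4$
points. The dumbbell form factors of the published geometries fall to
$\sim 10^{-4} I(0)$ in their minima near $Q \approx 0.18$/A, so *relative*
agreement at such minima is limited by the oracle, not by the model:
seed-to-seed spread of the estimator there is tens of percent, and
quasi-random and lattice clouds of the same size do no better. The test
suite therefore asserts two things: the strict 2% relative-agreement
band over $Q \in [0.005, 0.3]$/A (which the point-set oracle cannot meet
in the deep minima — that check documents the oracle's resolution
limit), and statistical consistency everywhere at the oracle's own
resolution (within 2% or 4 standard errors, SEs estimated from
independent sub-clouds), which holds for both published geometries.

## Guinier and Porod analysis

`guinier_fit` performs the weighted regression of $\ln I$ on $Q^2$ with
a self-consistent window $Q\,R_g \le 1.3$ (iterated from the lowest-$Q$
points until the window stabilises; the measured curves give no window,
so the conventional globular-particle limit is used). `porod_exponent`
is the negative weighted log–log slope over a user-chosen window; flat
background must be subtracted first, and nonpositive intensities in the
window are an error for exactly that reason. Guinier $R_g$ of noise-free
model curves agrees with the Monte-Carlo $R_g$ of the same geometry
within 3% for both published geometries.

`compare_shapes` deliberately reports *several* size measures — axial
length $d + 2a$, equatorial diameter, envelope volume, Monte-Carlo
$R_g$ — as percent differences, without electing any single one as "the"
size: the published ~9% length difference is consistent with the axial
lengths of the printed geometries (+7.8%) but the measure behind the
summary figure is not stated, so the report keeps all candidates
side by side. The Monte-Carlo $R_g$ of both geometries uses common
random numbers, so identical geometries compare to exactly 0%.

## The synthetic-data generator

The measured reduced curves are not published, so the generator emulates
their statistical structure and stands in for them:

* $Q$ grid: 100 log-spaced points over 0.005–0.5/A — spanning the
  Guinier regime of 40–120 A particles through the Porod window, as a
  very-small-angle instrument with a white beam would cover.
* Noise: $\sigma_I = 0.03\,I + 10^{-4} I(0)$, Gaussian, seeded. 3%
  fractional noise with a small floor is a realistic figure for a 1–2 h
  measurement of a dilute protein solution; no counting statistics are
  published, so this is a declared convention of the package.
* Scenarios (`fixture_suite`): KaiC and anKaiC dumbbell curves from the
  published geometries with scale factors 0.5 and 1.0 (encoding the
  reported two-fold difference in non-clustered scatterer density), and
  KaiA/anKaiA excluded-volume curves with $R_g$ = 3.4 and 8.6 nm and
  $m = 3$ ("Porod factor close to 3"). Each comes with a noise-free
  twin, and every curve embeds its generation parameters in its header.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about measured data: inter-particle structure factors,
oligomer mixtures (anKaiA's self-assembly enters only through its larger
$R_g$), wavelength-spread smearing beyond a per-point $\sigma_Q$, and
any mismatch between the dumbbell idealisation and the true protein
envelope. Recovery experiments demonstrate that the pipeline finds the
generating parameters of its own models under realistic noise; they
cannot certify the models themselves against reality.

## Problem sizes of the reproduction runs

The recovery experiments in `scripts/acceptance.R` (and the recovery
blocks of the test suite) simulate 100-point curves at 3% noise and fit
them with a swarm of 40 particles, 250 iterations and 2 restarts, using
24 orientation nodes and a 128 × 128 quadrature grid — roughly one to
two minutes per dumbbell fit on a single core, chosen so the whole
5-seed suite completes in minutes. Pilot runs at these settings recover
every free geometry parameter within ~3% (reduced $\chi^2$ 0.8–1.4, no
bounds hit); the larger `pso_config()` defaults change the recovered
values only marginally while costing roughly an order of magnitude more
time.

## Known limitations

* The closed-form dumbbell amplitude is quantitatively wrong for
  overlapping ellipsoids (it exists for speed and limit checks); the
  numeric amplitude is the reference everywhere.
* Relative model-vs-oracle comparisons are ill-conditioned at form-factor
  zero crossings; tests use denominators floored at a small fraction of
  the forward value, or statistical bounds, at such points.
* The scattering-length-density contrast is not modelled: `scale` is a
  free intensity scale ($I(0)-$background), not an absolute
  volume-normalised cross-section, because absolute contrasts for the
  measured samples are not published.
* No structure factor: the models are single-particle; clustering enters
  only through the phenomenological low-$Q$ power law.
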