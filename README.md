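# sansshape

Shape-model fitting for reduced 1-D small-angle scattering curves of
proteins in solution, built around two form-factor models:

* a **dumbbell model** for hexameric double-ring proteins — two identical
  coaxial ellipsoids of revolution (polar semi-axis *a*, equatorial
  semi-axes *r_eq*), centers a distance *d* apart, pierced by an axial
  cylindrical channel of radius *Rh* (the hexamer pore). Used for the
  circadian clock protein KaiC and its reconstructed ancestor anKaiC;
* the **polymer excluded-volume model** (Benoit self-avoiding chain,
  parameters *Rg* and Porod exponent *m* = 1/ν) for flexible or loosely
  assembled proteins such as KaiA and anKaiA.

The measured intensity is modelled as

    I(Q) = scale * <|F(Q,alpha)|^2> / <|F(0,alpha)|^2>
           + A_up * Q^-p + background

with `< >` the orientational average over the angle between the
scattering vector and the symmetry axis, and an optional additive
power law for the low-Q cluster upturn. Both published KaiC geometries
have interpenetrating ellipsoids (2a > d), so the package's reference
amplitude integrates the body's indicator function numerically — exactly,
including overlap and the hole — cast as precomputed Bessel/cosine
matrices times a geometry weight matrix so that a global particle-swarm
fit of the exact amplitude runs in minutes in pure R. A closed-form
superposition amplitude is retained for limit checks and speed, with a
warning in the overlap regime.

Around the models: chi-square particle-swarm fitting with box bounds,
restarts and per-point Gaussian resolution smearing; iterative Guinier
fits and Porod log-log slopes; Monte-Carlo volume/Rg and Debye pair-sum
oracles that validate every model result; a seeded synthetic-data
generator reproducing the statistical structure of reduced SANS curves;
and a small command-line front end
(`simulate / fit / analyze / compare / oracle`).

## Worked example

Simulate a 3%-noise curve from the published anKaiC dumbbell geometry
(d = 53 A, a = 35.4 A, r_eq = 45.5 A, Rh = 17.4 A) and recover the
geometry by a particle-swarm fit:

```r
library(sansshape)

truth <- reference_params("anKaiC")
q     <- make_q_grid()            # 100 log-spaced points, 0.005-0.5 1/A
curve <- simulate_curve("dumbbell", truth, q,
                        noise_model(0.03, 1e-4, seed = 7))
fit <- fit_dumbbell(curve, start = truth, n_alpha = 24,
                    config = pso_config(swarm_size = 40, iterations = 250,
                                        restarts = 2, seed = 11))
fit
#> PSO fit of the dumbbell model: chi2 = 82.38 (reduced 0.876, 100 points)
#>   free parameters: d, a, r_eq, Rh, scale, background
#>     d                 52.8  [26.5, 79.5]
#>     a                35.35  [17.7, 53.1]
#>     r_eq             45.68  [22.75, 68.25]
#>     Rh               17.44  [8.7, 26.1]
#>     scale            1.011  [0.5, 1.5]
#>     background   0.0009936  [0.0005, 0.0015]
#>   seed 11, 20080 evaluations, 2 restarts (best of 82.38, 82.38)
```

Every geometry parameter comes back within ~1% of the generating value
at a reduced chi-square of 0.88, with no parameter on a bound. The same
curve yields a model-free size estimate, and the two published
geometries can be compared directly:

```r
g <- guinier_fit(curve)
sprintf("Guinier Rg: %.1f A", g$rg)
#> [1] "Guinier Rg: 46.1 A"

compare_shapes(reference_params("KaiC"), reference_params("anKaiC"))
#> Dumbbell shape comparison (alt vs ref, percent difference)
#>   axial_length    +7.84 %   (ref 114.8, alt 123.8)
#>   equatorial      +2.25 %   (ref 89, alt 91)
#>   volume         +12.83 %   (ref 4.184e+05, alt 4.721e+05)
#>   rg              +4.63 %   (ref 42.35, alt 44.31)
#>   (Rg by Monte Carlo, n = 200000, seed 1)
```

The ancestral hexamer is longer than the contemporary one on every
measure; how much longer depends on the measure (axial length +7.8%,
Monte-Carlo Rg +4.6%), which is why `compare_shapes` reports all of
them instead of a single "size".

The command-line front end wraps the same functions:

```sh
Rscript inst/scripts/sansshape simulate --dir fixtures --seed 1
Rscript inst/scripts/sansshape fit --curve_file fixtures/ankaic_noisy.dat \
        --model dumbbell --seed 1
Rscript inst/scripts/sansshape analyze --curve_file fixtures/kaia_noisy.dat
```

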