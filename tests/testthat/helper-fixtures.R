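# Shared fixtures and a cross-file cache for expensive computations
# (reference model curves, swarm fits). Everything is seeded, so cached
# results are identical to freshly computed ones.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# geometry-only versions of the published parameter sets (scale 1, no
# background), used for oracle comparisons of the bare form factor
bare_geometry <- function(which) {
  p <- reference_params(which)
  dumbbell_params(p$d, p$a, p$r_eq, p$Rh)
}

# PSO settings used for recovery experiments in the tests: smaller than
# the pso_config() defaults so a fit takes ~1.5 min, with recovery quality
# still well inside the asserted tolerances
recovery_config <- function(seed) {
  pso_config(swarm_size = 40L, iterations = 250L, restarts = 2L,
             seed = seed)
}

# one seeded 3%-noise recovery experiment for a dumbbell protein;
# cached so several test blocks can interrogate the same fit
recovery_dumbbell <- function(which, seed = 1L) {
  cached(paste0("recovery_", which, "_", seed), {
    p <- reference_params(which)
    crv <- simulate_curve("dumbbell", p, make_q_grid(),
                          noise_model(0.03, 1e-4 * (p$scale + p$background),
                                      seed = 1000L + seed))
    fit_dumbbell(crv, start = p, n_alpha = 24L,
                 config = recovery_config(2000L + seed))
  })
}

recovery_polymer <- function(which, seed = 1L) {
  cached(paste0("recovery_", which, "_", seed), {
    p <- reference_params(which)
    crv <- simulate_curve("polymer_ev", p, make_q_grid(),
                          noise_model(0.03, 1e-4 * (p$scale + p$background),
                                      seed = 1000L + seed))
    fit_polymer_ev(crv, start = p, config = recovery_config(2000L + seed))
  })
}

# reference-quality numeric intensity of a bare geometry on the oracle Q grid
oracle_grid <- function() make_q_grid(0.005, 0.3, 60)

numeric_reference_curve <- function(which) {
  cached(paste0("numref_", which),
         dumbbell_intensity(oracle_grid(), bare_geometry(which)))
}

# self-term-corrected Debye intensity of a 2e4-point rejection-sampled cloud
debye_oracle_curve <- function(which) {
  cached(paste0("debye_", which), {
    cl <- sample_points(bare_geometry(which), 20000, seed = 2024)
    debye_intensity(cl, oracle_grid(), exact_max = 0L, dr = 0.05,
                    subtract_self = TRUE)
  })
}
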