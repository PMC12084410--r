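# Chi-square objective, resolution smearing and the particle swarm.

test_that("chi2 has the defining values and demands matching grids", {
  q <- make_q_grid(0.01, 0.1, 20)
  obs <- scattering_curve(q, q^-2, sigma_i = 0.05 * q^-2)
  expect_equal(chi2(obs, scattering_curve(q, obs$i)), 0)
  shifted <- scattering_curve(q, obs$i + obs$sigma_i)
  expect_equal(chi2(obs, shifted), 20)
  expect_error(chi2(obs, scattering_curve(q * 1.01, obs$i)), "grid")
  noerr <- scattering_curve(q, obs$i)
  expect_error(chi2(noerr, shifted), "sigma_i")
})

test_that("reduced chi-square at the true parameters is near 1 for 3% noise", {
  p <- reference_params("anKaiC")
  q <- make_q_grid()
  crv <- simulate_curve("dumbbell", p, q,
                        noise_model(0.03, 1e-4, seed = 77))
  model <- dumbbell_intensity(q, p)
  expect_gt(chi2(crv, model) / length(q), 0.6)
  expect_lt(chi2(crv, model) / length(q), 1.5)
})

test_that("smearing is the identity at zero width and fills in sharp minima", {
  p <- dumbbell_params(d = 80, a = 30, r_eq = 35, Rh = 0)
  q <- seq(0.005, 0.3, length.out = 800)
  crv <- dumbbell_intensity(q, p, n_alpha = 24, n_r = 96, n_z = 96)
  expect_identical(smear(crv, 0)$i, crv$i)
  sm <- smear(crv, 0.1 * q)
  idx <- which(q > 0.02 & q < 0.25)
  k <- idx[which.min(crv$i[idx])]  # deepest form-factor minimum
  expect_gt(sm$i[k], crv$i[k])
  expect_false(identical(sm$i, crv$i))
})

test_that("smearing agrees with a dense direct convolution oracle", {
  # smooth analytic test curve so the oracle integral is easy
  q <- seq(0.01, 0.3, length.out = 1200)
  f <- function(x) exp(-200 * (x - 0.15)^2) + 0.1
  crv <- scattering_curve(q, f(q))
  s <- 0.01
  sm <- smear(crv, s)
  # evaluate the oracle at the exact grid points used by smear
  q0s <- q[vapply(c(0.10, 0.15, 0.2), function(q0)
    which.min(abs(q - q0)), integer(1))]
  direct <- vapply(q0s, function(q0) {
    integrate(function(t) f(t) * dnorm(t, q0, s), q0 - 3 * s, q0 + 3 * s,
              rel.tol = 1e-10)$value /
      integrate(function(t) dnorm(t, q0, s), q0 - 3 * s, q0 + 3 * s,
                rel.tol = 1e-10)$value
  }, numeric(1))
  got <- sm$i[match(q0s, q)]
  expect_equal(got, direct, tolerance = 1e-4)
})

test_that("PSO solves a quadratic bowl, is deterministic, and its trace is
           non-increasing", {
  bowl <- function(x) sum((x - c(1.5, -2))^2)
  cfg <- pso_config(swarm_size = 25, iterations = 150, restarts = 2,
                    seed = 11)
  fit <- pso_minimize(bowl, c(-5, -5), c(5, 5), cfg)
  expect_lt(max(abs(fit$par - c(1.5, -2))), 1e-3 * 10)
  expect_true(all(diff(fit$trace) <= 0))
  fit2 <- pso_minimize(bowl, c(-5, -5), c(5, 5), cfg)
  expect_identical(fit, fit2)
})

test_that("PSO finds the Rastrigin basin", {
  rastrigin <- function(x) 20 + sum(x^2 - 10 * cos(2 * pi * x))
  fit <- pso_minimize(rastrigin, c(-5.12, -5.12), c(5.12, 5.12),
                      pso_config(swarm_size = 40, iterations = 200,
                                 restarts = 5, seed = 3))
  expect_lt(fit$value, 1.0)
})

test_that("polymer fit recovers noise-free curves essentially exactly", {
  p <- reference_params("KaiA")
  q <- make_q_grid()
  clean <- polymer_ev_intensity(q, p)
  crv <- scattering_curve(q, clean$i, sigma_i = 0.01 * clean$i)
  fit <- fit_polymer_ev(crv, start = p,
                        config = pso_config(swarm_size = 30,
                                            iterations = 400,
                                            restarts = 2, seed = 5))
  expect_lt(fit$chi2, 1e-6 * length(q))
  expect_equal(fit$best_params$rg, p$rg, tolerance = 1e-3)
})

test_that("dumbbell fit recovers a noise-free curve generated by its own
           operator", {
  p <- dumbbell_params(d = 80, a = 30, r_eq = 35, Rh = 10)
  q <- make_q_grid(0.005, 0.3, 60)
  clean <- dumbbell_intensity(q, p, method = "closed", n_alpha = 24)
  crv <- scattering_curve(q, clean$i, sigma_i = 0.01 * clean$i)
  fit <- fit_dumbbell(crv, start = p, free = c("d", "scale"),
                      bounds = list(d = c(70, 90), scale = c(0.8, 1.2)),
                      method = "closed", n_alpha = 24,
                      config = pso_config(swarm_size = 30, iterations = 300,
                                          restarts = 1, seed = 8))
  expect_lt(fit$chi2, 1e-6 * length(q))
  expect_equal(fit$best_params$d, 80, tolerance = 1e-3)
})

test_that("fits are invariant to a common rescaling of I and sigma_I", {
  p <- reference_params("KaiA")
  q <- make_q_grid(0.005, 0.5, 60)
  crv <- simulate_curve("polymer_ev", p, q, noise_model(0.03, 1e-4, seed = 6))
  c_fac <- 7.3
  scaled <- scattering_curve(q, c_fac * crv$i, sigma_i = c_fac * crv$sigma_i)
  start2 <- polymer_ev_params(p$rg, p$m, scale = c_fac * p$scale,
                              background = c_fac * p$background)
  cfg <- pso_config(swarm_size = 20, iterations = 150, restarts = 1,
                    seed = 4)
  f1 <- fit_polymer_ev(crv, start = p, config = cfg)
  f2 <- fit_polymer_ev(scaled, start = start2, config = cfg)
  expect_equal(f2$best_params$rg, f1$best_params$rg, tolerance = 1e-12)
  expect_equal(f2$best_params$m, f1$best_params$m, tolerance = 1e-12)
  expect_equal(f2$best_params$scale, c_fac * f1$best_params$scale,
               tolerance = 1e-12)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-12)
})

test_that("polymer parameter recovery over seeded replicates stays within 5%
           with no bound systematically hit", {
  p <- reference_params("KaiA")
  q <- make_q_grid()
  rel_err <- matrix(NA_real_, 20, 2, dimnames = list(NULL, c("rg", "m")))
  hits <- 0
  for (s in 1:20) {
    crv <- simulate_curve("polymer_ev", p, q,
                          noise_model(0.03, 1e-4, seed = 300 + s))
    fit <- fit_polymer_ev(crv, start = p,
                          config = pso_config(swarm_size = 30,
                                              iterations = 150,
                                              restarts = 1, seed = 400 + s))
    rel_err[s, ] <- abs(c(fit$best_params$rg / p$rg,
                          fit$best_params$m / p$m) - 1)
    hits <- hits + any(fit$bounds_hit)
  }
  expect_lt(median(rel_err[, "rg"]), 0.05)
  expect_lt(median(rel_err[, "m"]), 0.05)
  expect_lt(hits, 10)  # bounds are not systematically active
})

test_that("infeasible dumbbell bounds raise an error", {
  p <- reference_params("KaiC")
  crv <- simulate_curve("dumbbell", p, make_q_grid(0.01, 0.1, 12),
                        noise_model(0.03, 1e-4, seed = 1))
  expect_error(
    fit_dumbbell(crv, start = p, free = c("Rh"),
                 bounds = list(Rh = c(50, 60))),
    "feasible")
})

test_that("fit reports round-trip through JSON", {
  fit <- recovery_polymer("KaiA")
  f <- tempfile(fileext = ".json")
  write_fit_report(fit, f)
  rep <- read_fit_report(f)
  expect_equal(rep$model, "polymer_ev")
  expect_equal(rep$best_params$rg, fit$best_params$rg)
  expect_equal(rep$chi2, fit$chi2)
  expect_length(rep$convergence_trace, length(fit$convergence_trace))
})
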