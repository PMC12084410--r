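# Closed-form building blocks: sphere, ellipsoid, cylinder amplitudes and
# the assembled dumbbell amplitude.

test_that("sphere amplitude has the right limits, zero and closed-form values", {
  expect_equal(sphere_amplitude(0), 1)
  # first zero at the root of tan u = u
  expect_lt(abs(sphere_amplitude(4.4934)), 1e-4)
  expect_equal(sphere_amplitude(pi), 3 / pi^2, tolerance = 1e-12)
  # series and direct branches agree at the switch point
  expect_equal(sphere_amplitude(1e-2 - 1e-9), sphere_amplitude(1e-2 + 1e-9),
               tolerance = 1e-9)
  expect_error(sphere_amplitude(-1))
})

test_that("ellipsoid amplitude degenerates to the sphere and handles views", {
  q <- seq(0, 0.3, length.out = 40)
  # polar view: only the polar semi-axis matters
  expect_equal(ellipsoid_amplitude(q, 0, a = 25, r_eq = 60),
               sphere_amplitude(q * 25))
  # sphere degeneracy at any angle
  for (al in c(0.3, 1.1, pi / 2))
    expect_equal(ellipsoid_amplitude(q, al, 30, 30), sphere_amplitude(q * 30))
  expect_equal(ellipsoid_amplitude(0, 0.7, 30, 50), 1)
  expect_error(ellipsoid_amplitude(0.1, 0.2, -5, 30))
})

test_that("cylinder amplitude factorises into sinc and Bessel parts", {
  q <- seq(0, 0.4, length.out = 30)
  expect_equal(cylinder_amplitude(0, 0.5, R = 15, L = 100), 1)
  x <- q[-1] * 15
  expect_equal(cylinder_amplitude(q[-1], pi / 2, 15, 100),
               2 * besselJ(x, 1) / x)
  expect_equal(cylinder_amplitude(q, 0, 15, 100), sinc(q * 50))
  expect_error(cylinder_amplitude(0.1, 0.3, R = 0, L = 10))
})

test_that("closed dumbbell amplitude has the forward limit 2 V_e - V_c", {
  p <- reference_params("anKaiC")
  V_e <- 4 / 3 * pi * p$a * p$r_eq^2
  V_c <- pi * p$Rh^2 * p$L_tot
  expect_equal(dumbbell_amplitude_closed(0, 0.4, p), 2 * V_e - V_c)
  # coincident spheres, no hole: superposition of two spheres
  R <- 28
  sp <- dumbbell_params(0, R, R, 0)
  q <- seq(0, 0.3, length.out = 25)
  expect_equal(dumbbell_amplitude_closed(q, 0.9, sp),
               2 * (4 / 3 * pi * R^3) * sphere_amplitude(q * R))
})

test_that("closed dumbbell amplitude approximates the numeric one for the
           published overlapping geometry", {
  p <- reference_params("anKaiC")
  fc <- dumbbell_amplitude_closed(0.05, pi / 4, p)
  fn <- dumbbell_amplitude_numeric(0.05, pi / 4, p)
  # the overlap double-count bounds the discrepancy: both F(0) values are
  # within the overlap volume of each other, and at moderate q the
  # relative deviation stays of that order
  v_overlap <- attr(dumbbell_amplitude_numeric(0, 0, p), "volume")
  v_super <- 2 * (4 / 3 * pi * p$a * p$r_eq^2) - pi * p$Rh^2 * p$L_tot
  frac <- abs(v_super - v_overlap) / v_overlap
  expect_gt(frac, 0.01)  # the geometries really do overlap
  expect_lt(abs(fc - fn) / abs(fn), 3 * frac)
})

test_that("polymer excluded-volume form factor reduces to the Debye coil at
           m = 2 and has the right limits", {
  rg <- 3.4
  Q <- make_q_grid(0.001, 0.5, 120)
  x <- Q^2 * (10 * rg)^2
  debye_coil <- 2 * (exp(-x) - 1 + x) / x^2
  expect_lt(max(abs(sansshape:::polymer_ev_form(Q, rg, 2) - debye_coil)),
            1e-8)
  # closed-form value at Q^2 Rg^2 = 1
  expect_equal(sansshape:::polymer_ev_form(1 / 34, rg, 2), 2 * exp(-1),
               tolerance = 1e-10)
  p <- polymer_ev_params(rg, m = 3, scale = 2, background = 0.1)
  crv <- polymer_ev_intensity(c(1e-8, Q), p)
  expect_equal(crv$i[1], 2.1, tolerance = 1e-6)
  expect_error(polymer_ev_params(rg, m = 1))
})

test_that("polymer excluded-volume high-Q slope equals -m", {
  rg <- 3.4
  for (m in c(2.5, 3)) {
    crv <- polymer_ev_intensity(make_q_grid(5 / 34, 15 / 34, 40),
                                polymer_ev_params(rg, m))
    slope <- coef(lm(log(crv$i) ~ log(crv$q)))[2]
    expect_equal(unname(slope), -m, tolerance = 0.1 / m)
  }
})
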