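# Monte-Carlo sampling, volume/Rg estimators and the Debye pair sum.

test_that("rejection sampling honours the indicator and the seed", {
  p <- reference_params("anKaiC")
  cl <- sample_points(p, 2000, seed = 5)
  r <- sqrt(cl$xyz[, 1]^2 + cl$xyz[, 2]^2)
  expect_true(all(r >= p$Rh))         # nothing inside the 17.4 A channel
  expect_true(all(abs(cl$xyz[, 3]) <= p$d / 2 + p$a))
  u <- (abs(cl$xyz[, 3]) - p$d / 2) / p$a
  expect_true(all(r^2 <= p$r_eq^2 * (1 - u^2) + 1e-9))
  # sphere degeneracy: all points within R of the origin
  R <- 20
  cls <- sample_points(dumbbell_params(0, R, R, 0), 1500, seed = 2)
  expect_true(all(sqrt(rowSums(cls$xyz^2)) <= R + 1e-9))
  # determinism
  expect_identical(sample_points(p, 500, seed = 9)$xyz,
                   sample_points(p, 500, seed = 9)$xyz)
  # and the global RNG stream is left untouched
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(sample_points(p, 100, seed = 4))
  expect_identical(rnorm(1), before)
})

test_that("Monte-Carlo volume matches closed forms within 3 standard errors", {
  R <- 10
  v <- mc_volume(dumbbell_params(0, R, R, 0), n = 4e5, seed = 7)
  expect_lt(abs(v$volume - 4 / 3 * pi * R^3), 3 * v$se)
  # separated dumbbell without hole: twice the ellipsoid volume
  p <- dumbbell_params(d = 90, a = 30, r_eq = 35, Rh = 0)
  v2 <- mc_volume(p, n = 4e5, seed = 8)
  expect_lt(abs(v2$volume - 2 * 4 / 3 * pi * 30 * 35^2), 3 * v2$se)
})

test_that("Monte-Carlo Rg matches closed forms within 3 standard errors", {
  R <- 10
  rg <- mc_rg(dumbbell_params(0, R, R, 0), n = 2e5, seed = 3)
  expect_lt(abs(rg$rg - sqrt(3 / 5) * R), 3 * rg$se)
  expect_lt(max(abs(rg$centroid)), 5 * R / sqrt(2e5))
  # solid ellipsoid: Rg^2 = (a^2 + b^2 + c^2) / 5
  rg2 <- mc_rg(dumbbell_params(0, 50, 30, 0), n = 2e5, seed = 4)
  expect_lt(abs(rg2$rg - sqrt((50^2 + 30^2 + 30^2) / 5)), 3 * rg2$se)
})

test_that("Monte-Carlo standard errors shrink like n^(-1/2)", {
  p <- reference_params("KaiC")
  v1 <- mc_volume(p, n = 5e4, seed = 31)
  v2 <- mc_volume(p, n = 1e5, seed = 32)
  expect_lt(v2$se, v1$se)
  expect_gt(v2$se, v1$se / 2)
  r1 <- mc_rg(p, n = 5e4, seed = 33)
  r2 <- mc_rg(p, n = 1e5, seed = 34)
  expect_lt(r2$se, r1$se)
  expect_gt(r2$se, r1$se / 2)
})

test_that("degenerate geometries fail with an acceptance-rate diagnostic", {
  # a hair-thin shell: hole radius just below the equatorial radius
  thin <- dumbbell_params(0, 40, 40, 39.99)
  expect_error(mc_volume(thin, n = 1e5, seed = 1), "acceptance rate")
})

test_that("Debye sum reproduces closed forms for tiny point sets", {
  Q <- make_q_grid(0.01, 0.5, 30)
  one <- debye_intensity(matrix(c(1, 2, 3), 1, 3), Q)
  expect_equal(one$i, rep(1, 30))
  two <- debye_intensity(rbind(c(0, 0, 0), c(0, 0, 25)), Q)
  expect_equal(two$i, (1 + sinc(Q * 25)) / 2, tolerance = 1e-12)
  expect_true(all(two$i <= 1))
})

test_that("Debye intensity is 1 at q = 0 and bounded by 1 for real clouds,
           and the histogram path agrees with the exact path", {
  p <- reference_params("KaiC")
  cl <- sample_points(p, 1200, seed = 13)
  Q <- c(1e-9, make_q_grid(0.01, 0.3, 25))
  exact <- debye_intensity(cl, Q)
  expect_equal(exact$i[1], 1, tolerance = 1e-10)
  expect_true(all(exact$i <= 1 + 1e-12))
  hist <- debye_intensity(cl, Q, exact_max = 0L, dr = 0.05)
  expect_lt(max(abs(hist$i - exact$i)), 2e-4)
})

test_that("Guinier expansion of the Debye sum reproduces the Monte-Carlo Rg", {
  p <- bare_geometry("anKaiC")
  cl <- sample_points(p, 3000, seed = 17)
  rg_true <- cached("mcrg_anKaiC", mc_rg(p, n = 2e5, seed = 21))$rg
  q <- make_q_grid(0.004, 1.2 / rg_true, 30)
  deb <- debye_intensity(cl, q)
  g <- guinier_fit(scattering_curve(q, deb$i), qrg_max = 1.2)
  expect_equal(g$rg, rg_true, tolerance = 0.03)
})

test_that("XYZ export writes a well-formed file", {
  cl <- sample_points(reference_params("KaiC"), 50, seed = 1)
  f <- tempfile(fileext = ".xyz")
  write_xyz(cl, f)
  lines <- readLines(f)
  expect_equal(as.integer(lines[1]), 50)
  expect_length(lines, 52)
  got <- read.table(text = lines[-(1:2)])
  expect_equal(as.matrix(got[, 2:4]), unname(cl$xyz), tolerance = 1e-4,
               ignore_attr = TRUE)
})
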