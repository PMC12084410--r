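#' Noise model for simulated scattering curves
#'
#' Fractional-plus-floor Gaussian noise:
#' `sigma_I = fraction * I_model + floor`, with
#' `I_obs = I_model + N(0, sigma_I)`. The stored `sigma_i` column of a
#' simulated curve equals this model's sigma exactly, so simulated data
#' are honest about their own uncertainty.
#'
#' @param fraction fractional noise level `f >= 0` (0.03 emulates a 1-2 h
#'   SANS measurement of a dilute protein solution).
#' @param floor absolute intensity floor `>= 0` added to every sigma.
#' @param seed integer RNG seed for the Gaussian draws.
#' @return a list of class `noise_model`.
#' @export
noise_model <- function(fraction = 0.03, floor = 0, seed = 1L) {
  if (fraction < 0 || floor < 0) stop("fraction and floor must be >= 0")
  structure(list(fraction = fraction, floor = floor, seed = as.integer(seed)),
            class = "noise_model")
}

#' Momentum-transfer grid
#'
#' Strictly increasing Q grid, log- or linearly spaced. The default
#' (100 log-spaced points over 0.005-0.5 1/Angstrom) spans the Guinier
#' regime of 40-120 Angstrom particles and the Porod window used by
#' [porod_exponent()].
#'
#' @param qmin,qmax grid limits in 1/Angstrom, `0 < qmin < qmax`.
#' @param n number of points (>= 2; >= 10 for analysis-grade grids).
#' @param spacing `"log"` or `"linear"`.
#' @return numeric vector of length `n`.
#' @export
make_q_grid <- function(qmin = 0.005, qmax = 0.5, n = 100L,
                        spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (!(qmin > 0 && qmax > qmin)) stop("need 0 < qmin < qmax")
  if (n < 2) stop("n must be >= 2")
  if (spacing == "log") exp(seq(log(qmin), log(qmax), length.out = n))
  else seq(qmin, qmax, length.out = n)
}

#' Simulate a reduced scattering curve
#'
#' Evaluates the requested model (dumbbell at reference quadrature
#' quality, or polymer excluded-volume) on a Q grid and adds seeded
#' Gaussian noise per the [noise_model()]. With `fraction = floor = 0` the
#' model curve is returned exactly (with zero `sigma_i`).
#'
#' @param model `"dumbbell"` or `"polymer_ev"`.
#' @param params matching [dumbbell_params()] / [polymer_ev_params()].
#' @param q Q grid, 1/Angstrom.
#' @param noise a [noise_model()].
#' @param label curve label.
#' @return a [scattering_curve()] with generation metadata attached.
#' @export
simulate_curve <- function(model = c("dumbbell", "polymer_ev"), params,
                           q = make_q_grid(), noise = noise_model(),
                           label = model) {
  model <- match.arg(model)
  clean <- if (model == "dumbbell") dumbbell_intensity(q, params)
  else polymer_ev_intensity(q, params)
  si <- noise$fraction * clean$i + noise$floor
  i_obs <- if (all(si == 0)) clean$i
  else with_seed(noise$seed, clean$i + stats::rnorm(length(q), 0, si))
  pl <- unclass(params)
  meta <- pl[vapply(pl, function(v)
    is.numeric(v) && length(v) == 1, logical(1))]
  meta <- c(list(model = model), meta,
            list(noise_fraction = noise$fraction, noise_floor = noise$floor,
                 noise_seed = noise$seed))
  scattering_curve(q, i_obs, sigma_i = si, label = label[1],
                   metadata = meta)
}

#' Synthetic fixture curves for the clock-protein scenarios
#'
#' Generates the standard synthetic data set mirroring the four measured
#' proteins: dumbbell curves for KaiC and anKaiC from the published fitted
#' geometries, and polymer excluded-volume curves for KaiA and anKaiA from
#' the published radii of gyration with Porod exponent 3. Each scenario
#' comes as a noisy curve (3% fractional noise plus a floor of
#' `1e-4 * I(0)`) and a noise-free twin; generation parameters are
#' embedded in each curve's metadata (and written as `#` headers by
#' [write_sans_curve()]).
#'
#' @param seed integer seed; each curve derives its own sub-seed from it.
#' @param dir optional directory; when given, the eight curves are written
#'   as ASCII files named `<scenario>_{noisy,clean}.dat`.
#' @param q Q grid shared by all curves.
#' @return named list of eight [scattering_curve()]s
#'   (`kaic_noisy`, `kaic_clean`, ..., `ankaia_clean`), invisibly
#'   augmented with the file paths when `dir` is given.
#' @export
fixture_suite <- function(seed = 1L, dir = NULL, q = make_q_grid()) {
  scen <- list(
    kaic = list(model = "dumbbell", params = reference_params("KaiC")),
    ankaic = list(model = "dumbbell", params = reference_params("anKaiC")),
    kaia = list(model = "polymer_ev", params = reference_params("KaiA")),
    ankaia = list(model = "polymer_ev", params = reference_params("anKaiA"))
  )
  out <- list()
  for (k in seq_along(scen)) {
    s <- scen[[k]]
    name <- names(scen)[k]
    i0 <- s$params$scale + s$params$background
    nm <- noise_model(fraction = 0.03, floor = 1e-4 * i0,
                      seed = seed * 100L + k)
    out[[paste0(name, "_noisy")]] <-
      simulate_curve(s$model, s$params, q, nm,
                     label = paste0(name, " (3% noise)"))
    out[[paste0(name, "_clean")]] <-
      simulate_curve(s$model, s$params, q, noise_model(0, 0, seed = 0L),
                     label = paste0(name, " (noise-free)"))
  }
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character(0)
    for (nm in names(out)) {
      p <- file.path(dir, paste0(nm, ".dat"))
      write_sans_curve(out[[nm]], p)
      paths[nm] <- p
    }
    attr(out, "paths") <- paths
  }
  out
}
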