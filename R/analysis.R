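#' Guinier fit of a scattering curve
#'
#' Estimates the radius of gyration from the low-Q Guinier regime,
#' `I(Q) = I(0) exp(-Q^2 Rg^2 / 3)`, by weighted linear regression of
#' `ln I` on `Q^2`. The fitting window is determined self-consistently:
#' starting from the lowest-Q points, the fit is iterated until the set of
#' points with `Q * Rg <= qrg_max` implied by the fitted Rg stops
#' changing.
#'
#' @param curve a [scattering_curve()].
#' @param qrg_max upper limit of `Q * Rg` defining the Guinier window
#'   (conventionally 1.3 for globular particles).
#' @param min_points minimum number of points required in the window.
#' @param max_iter iteration cap for the window search.
#' @return a list with `rg` (Angstrom), `i0` (forward intensity),
#'   `window` (indices of the points used) and `n_iter`.
#' @export
guinier_fit <- function(curve, qrg_max = 1.3, min_points = 5L,
                        max_iter = 50L) {
  stopifnot(inherits(curve, "scattering_curve"))
  q <- curve$q; i <- curve$i; si <- curve$sigma_i
  pos <- i > 0
  if (sum(pos) < min_points) stop("too few positive intensities for a Guinier fit")
  # ln I uncertainties: sigma_I / I when available, else unweighted
  wts <- function(idx) {
    s <- si[idx]
    if (all(s > 0)) (i[idx] / s)^2 else rep(1, length(idx))
  }
  fit_window <- function(idx) {
    fit <- stats::lm.wfit(cbind(1, q[idx]^2), log(i[idx]), wts(idx))
    slope <- fit$coefficients[2]
    if (!is.finite(slope) || slope >= 0)
      stop("Guinier fit has non-negative slope; no Guinier regime in window")
    list(rg = sqrt(-3 * slope), i0 = exp(fit$coefficients[1]))
  }
  # initial window: out to where the intensity has decayed by ~40% (so the
  # starting slope estimate rides on real decay, not noise), else the
  # first half of the curve
  p_idx <- which(pos)
  drop_idx <- p_idx[i[p_idx] < 0.6 * i[p_idx[1]]]
  n0 <- if (length(drop_idx) > 0)
    max(min_points, match(drop_idx[1], p_idx)) else
      max(min_points, length(p_idx) %/% 2)
  idx <- p_idx[seq_len(min(n0, length(p_idx)))]
  last <- NULL
  for (it in seq_len(max_iter)) {
    f <- fit_window(idx)
    new_idx <- which(pos & q * f$rg <= qrg_max)
    if (length(new_idx) < min_points)
      stop(sprintf(paste0("no convergent Guinier window: only %d points ",
                          "satisfy Q*Rg <= %.2f (Rg = %.1f A); need %d"),
                   length(new_idx), qrg_max, f$rg, min_points))
    if (identical(new_idx, idx)) {
      return(list(rg = unname(f$rg), i0 = unname(f$i0), window = idx,
                  n_iter = it))
    }
    # guard against two-cycle oscillation of the window: of the two
    # cycling windows, the smaller one is self-consistent (its fit
    # implies a window at least as large as itself)
    if (identical(new_idx, last)) {
      idx <- if (length(new_idx) < length(idx)) new_idx else idx
      f <- fit_window(idx)
      return(list(rg = unname(f$rg), i0 = unname(f$i0), window = idx,
                  n_iter = it))
    }
    last <- idx
    idx <- new_idx
  }
  stop("Guinier window did not stabilise within max_iter iterations")
}

#' Porod exponent of a scattering curve
#'
#' Negative slope of the weighted log-log regression of intensity on Q
#' over a high-Q window: ~4 for compact sharp-interface particles, ~3 or
#' below for polymer-like or loosely packed objects. Any flat background
#' must be subtracted before calling; nonpositive intensities in the
#' window are an error for that reason.
#'
#' @param curve a [scattering_curve()].
#' @param q_window numeric length-2 vector `c(qlo, qhi)` in 1/Angstrom;
#'   must contain at least `min_points` curve points.
#' @param min_points minimum points in the window.
#' @return the Porod exponent (positive for decaying curves).
#' @export
porod_exponent <- function(curve, q_window, min_points = 5L) {
  stopifnot(inherits(curve, "scattering_curve"), length(q_window) == 2)
  idx <- which(curve$q >= q_window[1] & curve$q <= q_window[2])
  if (length(idx) < min_points)
    stop(sprintf("Porod window [%g, %g] contains %d points; need >= %d",
                 q_window[1], q_window[2], length(idx), min_points))
  i <- curve$i[idx]
  if (any(i <= 0))
    stop(paste("nonpositive intensities in the Porod window;",
               "subtract the background first"))
  s <- curve$sigma_i[idx]
  w <- if (all(s > 0)) (i / s)^2 else rep(1, length(idx))
  fit <- stats::lm.wfit(cbind(1, log(curve$q[idx])), log(i), w)
  -unname(fit$coefficients[2])
}

#' Compare two dumbbell geometries
#'
#' Reports the relative difference between two dumbbell geometries for
#' several candidate size measures: total axial length `d + 2a`,
#' equatorial diameter, envelope volume (from the exact quadrature
#' weights) and Monte-Carlo radius of gyration. Each is given as a percent
#' difference of `alt` relative to `ref`; no single measure is singled out
#' as "the" size, since length-, volume- and Rg-based comparisons answer
#' different questions.
#'
#' @param params_ref,params_alt [dumbbell_params()] objects (reference and
#'   alternative geometry).
#' @param n_mc Monte-Carlo sample size for the Rg comparison.
#' @param seed RNG seed for the Monte-Carlo draws.
#' @return an object of class `shape_comparison`: a list of percent
#'   differences `axial_length`, `equatorial`, `volume`, `rg`, plus the
#'   underlying absolute values.
#' @export
compare_shapes <- function(params_ref, params_alt, n_mc = 2e5, seed = 1L) {
  stopifnot(inherits(params_ref, "dumbbell_params"),
            inherits(params_alt, "dumbbell_params"))
  pct <- function(alt, ref) 100 * (alt - ref) / ref
  vol <- function(p) {
    # exact volume of the indicator body via the radial annulus integral
    f <- dumbbell_quadrature(0, 0, p$r_eq, p$d / 2 + p$a, 512L, 512L)
    attr(f(p$d, p$a, p$r_eq, p$Rh), "volume")
  }
  # common random numbers: the same seed for both geometries, so identical
  # inputs give exactly 0% and the difference estimate has lower variance
  rg_ref <- mc_rg(params_ref, n = n_mc, seed = seed)
  rg_alt <- mc_rg(params_alt, n = n_mc, seed = seed)
  values <- list(
    axial_length = c(ref = params_ref$L_tot, alt = params_alt$L_tot),
    equatorial = c(ref = 2 * params_ref$r_eq, alt = 2 * params_alt$r_eq),
    volume = c(ref = vol(params_ref), alt = vol(params_alt)),
    rg = c(ref = rg_ref$rg, alt = rg_alt$rg)
  )
  out <- list(
    percent = vapply(values, function(v) pct(v["alt"], v["ref"]),
                     numeric(1)),
    values = values,
    rg_se = c(ref = rg_ref$se, alt = rg_alt$se),
    seed = seed, n_mc = n_mc
  )
  names(out$percent) <- names(values)
  class(out) <- "shape_comparison"
  out
}

#' @export
print.shape_comparison <- function(x, ...) {
  cat("Dumbbell shape comparison (alt vs ref, percent difference)\n")
  for (k in names(x$percent)) {
    v <- x$values[[k]]
    cat(sprintf("  %-13s %+7.2f %%   (ref %.4g, alt %.4g)\n",
                k, x$percent[[k]], v["ref"], v["alt"]))
  }
  cat(sprintf("  (Rg by Monte Carlo, n = %g, seed %d)\n", x$n_mc, x$seed))
  invisible(x)
}
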