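#' Chi-square between a measured and a model curve
#'
#' `sum(((I_obs - I_model) / sigma_I)^2)` over the shared Q grid. The two
#' curves must be sampled on the same grid and the observed curve must
#' carry strictly positive uncertainties.
#'
#' @param curve observed [scattering_curve()] with `sigma_i > 0`.
#' @param model_curve model [scattering_curve()] on the identical Q grid.
#' @return the chi-square statistic (dimensionless scalar).
#' @export
chi2 <- function(curve, model_curve) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(model_curve, "scattering_curve"))
  if (length(curve$q) != length(model_curve$q) ||
      max(abs(curve$q / model_curve$q - 1)) > 1e-8)
    stop("curve and model_curve are not on the same Q grid")
  if (any(curve$sigma_i <= 0))
    stop("chi2 requires strictly positive sigma_i on the observed curve")
  sum(((curve$i - model_curve$i) / curve$sigma_i)^2)
}

#' Gaussian resolution smearing of a model curve
#'
#' Convolves a model intensity curve with a per-point Gaussian resolution
#' kernel in Q (width `sigma_q`, truncated at +/- 3 sigma), approximating
#' instrumental resolution. The convolution is carried out on the curve's
#' own grid with trapezoidal weights, renormalised per point so truncation
#' and grid edges do not leak intensity. Points with `sigma_q = 0` are
#' returned unchanged.
#'
#' @param model_curve a [scattering_curve()] (reasonably densely sampled).
#' @param sigma_q per-point Gaussian widths in 1/Angstrom (scalar or
#'   vector, >= 0).
#' @return the smeared [scattering_curve()], with `sigma_q` recorded.
#' @export
smear <- function(model_curve, sigma_q) {
  stopifnot(inherits(model_curve, "scattering_curve"))
  q <- model_curve$q; i <- model_curve$i
  n <- length(q)
  sigma_q <- rep_len(sigma_q, n)
  if (any(sigma_q < 0)) stop("sigma_q must be >= 0")
  if (all(sigma_q == 0)) return(model_curve)
  dq <- c(diff(q)[1], (q[-(1:2)] - q[1:(n - 2)]) / 2, diff(q)[n - 1])
  out <- i
  for (k in which(sigma_q > 0)) {
    s <- sigma_q[k]
    j <- which(abs(q - q[k]) <= 3 * s)
    w <- exp(-(q[j] - q[k])^2 / (2 * s^2)) * dq[j]
    out[k] <- sum(w * i[j]) / sum(w)
  }
  scattering_curve(q, out, sigma_i = model_curve$sigma_i, sigma_q = sigma_q,
                   label = model_curve$label, metadata = model_curve$metadata)
}

#' Particle-swarm optimizer configuration
#'
#' Hyperparameters of the global-best particle swarm used for curve
#' fitting: inertia `w`, cognitive (`c1`) and social (`c2`) acceleration,
#' swarm size, iteration count, independent restarts, and a velocity clamp
#' expressed as a fraction of each parameter's box width.
#'
#' @param swarm_size number of particles (>= 10).
#' @param iterations velocity/position updates per restart.
#' @param inertia inertia weight `w`, in (0, 1).
#' @param cognitive,social acceleration coefficients `c1`, `c2` (> 0).
#' @param restarts independent swarm runs; the best result is returned.
#' @param seed integer RNG seed; restart `k` uses `seed + k - 1`.
#' @param velocity_clamp maximum |velocity| per parameter as a fraction of
#'   the box width.
#' @return a list of class `pso_config`.
#' @export
pso_config <- function(swarm_size = 50L, iterations = 500L, inertia = 0.72,
                       cognitive = 1.49, social = 1.49, restarts = 5L,
                       seed = 1L, velocity_clamp = 0.5) {
  if (swarm_size < 10) stop("swarm_size must be >= 10")
  if (inertia <= 0 || inertia >= 1) stop("inertia must be in (0, 1)")
  if (cognitive <= 0 || social <= 0) stop("c1 and c2 must be > 0")
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 cognitive = cognitive, social = social,
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 velocity_clamp = velocity_clamp), class = "pso_config")
}

#' Global-best particle swarm minimisation
#'
#' Standard global-best PSO over a box: velocities follow
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)`, positions are
#' clipped to the box with the corresponding velocity component zeroed at
#' the wall, and velocities are clamped to a fraction of the box width.
#' Runs `restarts` independent swarms and returns the best. Fully
#' deterministic given `config$seed` (the caller's RNG state is left
#' untouched).
#'
#' @param objective function mapping a parameter vector to a finite scalar
#'   (larger = worse); may return `Inf` as a penalty.
#' @param lower,upper numeric vectors of box bounds (`lower < upper`).
#' @param config a [pso_config()].
#' @return a list of class `pso_fit`: `par`, `value`, `trace` (best value
#'   per iteration of the winning restart, non-increasing),
#'   `restart_values`, `bounds_hit` (logical per parameter), `n_evals`,
#'   `seed`, `lower`, `upper`.
#' @export
pso_minimize <- function(objective, lower, upper, config = pso_config()) {
  stopifnot(length(lower) == length(upper), all(lower < upper))
  npar <- length(lower)
  rng <- upper - lower
  vmax <- config$velocity_clamp * rng
  one_run <- function(run_seed) with_seed(run_seed, {
    ns <- config$swarm_size
    X <- lower + matrix(stats::runif(npar * ns), npar, ns) * rng
    V <- matrix(stats::runif(npar * ns, -1, 1), npar, ns) * vmax
    f <- apply(X, 2, objective)
    if (all(is.na(f))) stop("objective returned NaN for the whole swarm")
    f[is.na(f)] <- Inf
    Pb <- X; fPb <- f
    g <- which.min(f)
    gbest <- X[, g]; fg <- f[g]
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      r1 <- matrix(stats::runif(npar * ns), npar, ns)
      r2 <- matrix(stats::runif(npar * ns), npar, ns)
      V <- config$inertia * V + config$cognitive * r1 * (Pb - X) +
        config$social * r2 * (gbest - X)
      V <- pmin(pmax(V, -vmax), vmax)
      X <- X + V
      low_hit <- X < lower; up_hit <- X > upper
      X[low_hit] <- lower[row(X)[low_hit]]
      X[up_hit] <- upper[row(X)[up_hit]]
      V[low_hit | up_hit] <- 0
      f <- apply(X, 2, objective)
      f[is.na(f)] <- Inf
      imp <- f < fPb
      Pb[, imp] <- X[, imp]; fPb[imp] <- f[imp]
      g <- which.min(fPb)
      if (fPb[g] < fg) { fg <- fPb[g]; gbest <- Pb[, g] }
      trace[it] <- fg
    }
    list(par = gbest, value = fg, trace = trace)
  })
  runs <- lapply(seq_len(config$restarts),
                 function(k) one_run(config$seed + k - 1L))
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  structure(list(
    par = best$par, value = best$value, trace = best$trace,
    restart_values = vals,
    bounds_hit = (best$par - lower < 1e-8 * rng) |
      (upper - best$par < 1e-8 * rng),
    n_evals = config$restarts * config$swarm_size *
      (config$iterations + 1L),
    seed = config$seed, lower = lower, upper = upper
  ), class = "pso_fit")
}

# Default +/-50% box around a starting value; zero-valued parameters get a
# one-sided box scaled by `fallback`.
default_bounds <- function(value, fallback) {
  if (value != 0) sort(c(0.5 * value, 1.5 * value)) else c(0, fallback)
}

# Build (lower, upper) vectors for the free parameters.
resolve_bounds <- function(free, start_values, bounds, fallbacks) {
  lo <- hi <- numeric(length(free)); names(lo) <- names(hi) <- free
  for (p in free) {
    b <- if (!is.null(bounds[[p]])) bounds[[p]]
    else default_bounds(start_values[[p]], fallbacks[[p]])
    if (length(b) != 2 || b[1] >= b[2])
      stop("invalid bounds for parameter '", p, "'")
    lo[p] <- b[1]; hi[p] <- b[2]
  }
  list(lower = lo, upper = hi)
}

finish_fit <- function(pso, curve, free, best_params, model_curve, model_id) {
  n <- length(curve$q)
  structure(list(
    model = model_id, best_params = best_params, free = free,
    chi2 = pso$value, reduced_chi2 = pso$value / (n - length(free)),
    n_points = n, convergence_trace = pso$trace,
    restart_values = pso$restart_values,
    bounds_hit = stats::setNames(pso$bounds_hit, free),
    lower = pso$lower, upper = pso$upper, seed = pso$seed,
    n_evals = pso$n_evals, fitted_curve = model_curve
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("PSO fit of the %s model: chi2 = %.4g (reduced %.3g, %d points)\n",
              x$model, x$chi2, x$reduced_chi2, x$n_points))
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  bp <- x$best_params
  for (p in x$free)
    cat(sprintf("    %-11s %10.4g  [%g, %g]%s\n", p, bp[[p]],
                x$lower[[p]], x$upper[[p]],
                if (x$bounds_hit[[p]]) "  <- at bound" else ""))
  cat(sprintf("  seed %d, %d evaluations, %d restarts (best of %s)\n",
              x$seed, x$n_evals, length(x$restart_values),
              paste(signif(x$restart_values, 4), collapse = ", ")))
  invisible(x)
}

#' Fit the dumbbell model to a scattering curve by PSO
#'
#' Particle-swarm fit of the dumbbell model (numeric indicator amplitude
#' by default) to a reduced curve, minimising the chi-square against
#' `sigma_i`. Any subset of `{d, a, r_eq, Rh, scale, background,
#' upturn_amplitude, upturn_exponent}` may be free; the remaining
#' parameters are held at their `start` values. Default bounds are
#' +/- 50% boxes around the start. If the curve carries `sigma_q`, the
#' model is resolution-smeared before comparison.
#'
#' The orientation-and-grid quadrature tables are precomputed once for the
#' whole swarm (the Bessel and cosine factors depend only on the data Q
#' grid and the bound box), so each particle costs one geometry-weight
#' matrix and one matrix product.
#'
#' @param curve observed [scattering_curve()] with positive `sigma_i`.
#' @param start a [dumbbell_params()] with starting/fixed values.
#' @param bounds optional named list of `c(lo, hi)` per free parameter.
#' @param free character vector of free parameter names.
#' @param config a [pso_config()].
#' @param method `"numeric"` (exact indicator amplitude) or `"closed"`
#'   (fast superposition approximation).
#' @param n_alpha orientation quadrature nodes used during fitting.
#' @param n_r,n_z quadrature grid for the numeric amplitude during
#'   fitting.
#' @return a `fit_result`; `best_params` is a [dumbbell_params()].
#' @export
fit_dumbbell <- function(curve, start, bounds = NULL,
                         free = c("d", "a", "r_eq", "Rh", "scale",
                                  "background"),
                         config = pso_config(),
                         method = c("numeric", "closed"),
                         n_alpha = 32L, n_r = 128L, n_z = 128L) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(start, "dumbbell_params"))
  method <- match.arg(method)
  all_names <- c("d", "a", "r_eq", "Rh", "scale", "background",
                 "upturn_amplitude", "upturn_exponent")
  if (!all(free %in% all_names))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, all_names), collapse = ", "))
  fallbacks <- list(d = start$a, a = start$a, r_eq = start$r_eq,
                    Rh = 0.5 * start$r_eq, scale = 1,
                    background = 1e-2 * max(start$scale, 1e-12),
                    upturn_amplitude = 1e-3 * max(start$scale, 1e-12),
                    upturn_exponent = 4)
  bb <- resolve_bounds(free, start, bounds, fallbacks)
  if ("Rh" %in% free && !("r_eq" %in% free) &&
      bb$lower[["Rh"]] >= start$r_eq)
    stop("bounds exclude any feasible geometry: Rh >= r_eq everywhere")
  Q <- curve$q
  gl <- gl_nodes(n_alpha, 0, pi / 2)
  w_alpha <- gl$w * sin(gl$x)
  fixed <- stats::setNames(as.numeric(start[all_names]), all_names)
  hiv <- function(p) if (p %in% free) bb$upper[[p]] else fixed[[p]]
  if (method == "numeric") {
    quad <- dumbbell_quadrature(Q, gl$x, hiv("r_eq"),
                                hiv("d") / 2 + hiv("a"), n_r, n_z)
  } else {
    qs_alpha <- gl$x
  }
  shape_curve <- function(pv) {
    if (pv[["Rh"]] >= pv[["r_eq"]]) return(NULL)
    if (method == "numeric") {
      Fq <- quad(pv[["d"]], pv[["a"]], pv[["r_eq"]], pv[["Rh"]])
      V <- attr(Fq, "volume")
      if (!is.finite(V) || V <= 0) return(NULL)
      as.vector((Fq * Fq) %*% w_alpha) / V^2
    } else {
      p <- dumbbell_params(pv[["d"]], pv[["a"]], pv[["r_eq"]], pv[["Rh"]])
      Fq <- outer(Q, qs_alpha, function(qi, al)
        dumbbell_amplitude_closed(qi, al, p))
      F0 <- 2 * 4 / 3 * pi * p$a * p$r_eq^2 - pi * p$Rh^2 * p$L_tot
      as.vector((Fq * Fq) %*% w_alpha) / F0^2
    }
  }
  has_smear <- !is.null(curve$sigma_q) && any(curve$sigma_q > 0)
  objective <- function(x) {
    pv <- fixed
    pv[free] <- x
    S <- shape_curve(pv)
    if (is.null(S)) return(Inf)
    i_mod <- pv[["scale"]] * S + pv[["background"]]
    if (pv[["upturn_amplitude"]] > 0)
      i_mod <- i_mod + pv[["upturn_amplitude"]] * Q^(-pv[["upturn_exponent"]])
    if (has_smear)
      i_mod <- smear(scattering_curve(Q, i_mod), curve$sigma_q)$i
    sum(((curve$i - i_mod) / curve$sigma_i)^2)
  }
  pso <- pso_minimize(objective, bb$lower, bb$upper, config)
  pv <- fixed; pv[free] <- pso$par
  best <- dumbbell_params(pv[["d"]], pv[["a"]], pv[["r_eq"]], pv[["Rh"]],
                          scale = pv[["scale"]],
                          background = pv[["background"]],
                          upturn_amplitude = pv[["upturn_amplitude"]],
                          upturn_exponent = pv[["upturn_exponent"]])
  S <- shape_curve(pv)
  i_mod <- pv[["scale"]] * S + pv[["background"]]
  if (pv[["upturn_amplitude"]] > 0)
    i_mod <- i_mod + pv[["upturn_amplitude"]] * Q^(-pv[["upturn_exponent"]])
  if (has_smear) i_mod <- smear(scattering_curve(Q, i_mod), curve$sigma_q)$i
  finish_fit(pso, curve, free, best,
             scattering_curve(Q, i_mod, label = "dumbbell fit"),
             "dumbbell")
}

#' Fit the polymer excluded-volume model by PSO
#'
#' Particle-swarm fit of the excluded-volume polymer form factor, with any
#' subset of `{rg, m, scale, background}` free. Same conventions as
#' [fit_dumbbell()].
#'
#' @inheritParams fit_dumbbell
#' @param start a [polymer_ev_params()] (note `rg` in nm).
#' @return a `fit_result`; `best_params` is a [polymer_ev_params()].
#' @export
fit_polymer_ev <- function(curve, start, bounds = NULL,
                           free = c("rg", "m", "scale", "background"),
                           config = pso_config()) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(start, "polymer_ev_params"))
  all_names <- c("rg", "m", "scale", "background")
  if (!all(free %in% all_names))
    stop("unknown free parameter(s): ",
         paste(setdiff(free, all_names), collapse = ", "))
  fallbacks <- list(rg = 10, m = 4, scale = 1,
                    background = 1e-2 * max(start$scale, 1e-12))
  bb <- resolve_bounds(free, start, bounds, fallbacks)
  if ("m" %in% free) {
    # keep the exponent inside its physical range 1 < m <= 4
    bb$lower[["m"]] <- max(bb$lower[["m"]], 1.01)
    bb$upper[["m"]] <- min(bb$upper[["m"]], 4)
  }
  Q <- curve$q
  fixed <- stats::setNames(as.numeric(start[all_names]), all_names)
  has_smear <- !is.null(curve$sigma_q) && any(curve$sigma_q > 0)
  objective <- function(x) {
    pv <- fixed
    pv[free] <- x
    i_mod <- pv[["scale"]] * polymer_ev_form(Q, pv[["rg"]], pv[["m"]]) +
      pv[["background"]]
    if (has_smear)
      i_mod <- smear(scattering_curve(Q, i_mod), curve$sigma_q)$i
    sum(((curve$i - i_mod) / curve$sigma_i)^2)
  }
  pso <- pso_minimize(objective, bb$lower, bb$upper, config)
  pv <- fixed; pv[free] <- pso$par
  best <- polymer_ev_params(pv[["rg"]], pv[["m"]], pv[["scale"]],
                            pv[["background"]])
  i_mod <- pv[["scale"]] * polymer_ev_form(Q, pv[["rg"]], pv[["m"]]) +
    pv[["background"]]
  if (has_smear) i_mod <- smear(scattering_curve(Q, i_mod), curve$sigma_q)$i
  finish_fit(pso, curve, free, best,
             scattering_curve(Q, i_mod, label = "polymer EV fit"),
             "polymer_ev")
}

#' Serialise a fit result to a JSON report
#'
#' Writes a structured, human-readable report of a PSO fit: model, best
#' parameters, chi-square, seed, bounds, bound-hit flags and the
#' convergence trace.
#'
#' @param fit a `fit_result` from [fit_dumbbell()] or [fit_polymer_ev()].
#' @param path output file path (`.json`).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "fit_result"))
  bp <- unclass(fit$best_params)
  rep <- list(
    model = fit$model,
    best_params = bp[vapply(bp, is.numeric, logical(1))],
    free = as.list(stats::setNames(
      vapply(fit$free, function(p) bp[[p]], numeric(1)), fit$free)),
    chi2 = fit$chi2, reduced_chi2 = fit$reduced_chi2,
    n_points = fit$n_points, seed = fit$seed,
    bounds = list(lower = as.list(fit$lower), upper = as.list(fit$upper)),
    bounds_hit = as.list(fit$bounds_hit),
    restart_values = fit$restart_values,
    convergence_trace = fit$convergence_trace
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a JSON fit report
#'
#' @param path a report written by [write_fit_report()].
#' @return the report as a list.
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
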