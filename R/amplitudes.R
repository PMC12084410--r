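#' Sphere scattering amplitude
#'
#' Normalised scattering amplitude of a homogeneous sphere as a function of
#' the dimensionless product `u = q*R`:
#' `A(u) = 3 (sin u - u cos u) / u^3`, continuous at `u = 0` with value 1.
#' Building block for the ellipsoid amplitude.
#'
#' @param u numeric vector, `u = q*R >= 0`.
#' @return amplitude values in (-0.066, 1].
#' @export
sphere_amplitude <- function(u) {
  stopifnot(all(u >= 0))
  out <- numeric(length(u))
  small <- u < 1e-2
  us <- u[small]
  # series of 3(sin u - u cos u)/u^3 about 0
  out[small] <- 1 - us^2 / 10 + us^4 / 280
  ub <- u[!small]
  out[!small] <- 3 * (sin(ub) - ub * cos(ub)) / ub^3
  out
}

#' Ellipsoid-of-revolution scattering amplitude
#'
#' Amplitude of a homogeneous ellipsoid of revolution with polar semi-axis
#' `a` and equatorial semi-axes `r_eq`, at orientation angle `alpha`
#' between the scattering vector and the symmetry axis. Reduces to the
#' sphere amplitude with effective radius
#' `r_eff = sqrt(a^2 cos^2(alpha) + r_eq^2 sin^2(alpha))`.
#'
#' @param q momentum transfer, 1/Angstrom, vector allowed.
#' @param alpha orientation angle in radians, `0 <= alpha <= pi/2`
#'   (scalar, or vector if `q` is scalar).
#' @param a polar semi-axis, Angstrom (> 0).
#' @param r_eq equatorial semi-axis, Angstrom (> 0).
#' @return amplitude, 1 at `q = 0`.
#' @export
ellipsoid_amplitude <- function(q, alpha, a, r_eq) {
  if (a <= 0 || r_eq <= 0) stop("semi-axes must be > 0")
  stopifnot(all(q >= 0), all(alpha >= 0), all(alpha <= pi / 2))
  r_eff <- sqrt(a^2 * cos(alpha)^2 + r_eq^2 * sin(alpha)^2)
  sphere_amplitude(q * r_eff)
}

#' Cylinder scattering amplitude
#'
#' Amplitude of a homogeneous cylinder of radius `R` and length `L` at
#' orientation angle `alpha`:
#' `sinc(q L cos(alpha) / 2) * 2 J1(q R sin(alpha)) / (q R sin(alpha))`,
#' with both factors continued to 1 at their removable singularities.
#' Used for the axial channel of the dumbbell model.
#'
#' @inheritParams ellipsoid_amplitude
#' @param R cylinder radius, Angstrom (> 0).
#' @param L cylinder length, Angstrom (> 0).
#' @return amplitude, 1 at `q = 0`.
#' @export
cylinder_amplitude <- function(q, alpha, R, L) {
  if (R <= 0 || L <= 0) stop("cylinder R and L must be > 0")
  stopifnot(all(q >= 0))
  sinc(q * L * cos(alpha) / 2) * besinc(q * R * sin(alpha))
}

#' Closed-form dumbbell amplitude (superposition approximation)
#'
#' Amplitude (times volume, Angstrom^3) of the dumbbell body - two
#' identical coaxial ellipsoids of revolution with an axial cylindrical
#' hole - assembled by linear superposition:
#' `F = V_e * A_ell(q, alpha) * 2 cos(q d cos(alpha) / 2)
#'      - V_c * A_cyl(q, alpha; Rh, L_tot)`
#' with `V_e = (4/3) pi a r_eq^2`, `V_c = pi Rh^2 L_tot` and
#' `L_tot = d + 2a`.
#'
#' This expression is an APPROXIMATION whenever the two ellipsoids overlap
#' (`2a > d`): the overlap region is counted twice and the hole volume is
#' over-subtracted where the cylinder extends beyond the ellipsoid
#' surfaces. [dumbbell_amplitude_numeric()] is the exact reference; the
#' closed form is retained as a fast approximation and limit-check tool.
#'
#' @inheritParams ellipsoid_amplitude
#' @param params a [dumbbell_params()] object.
#' @return amplitude times volume, Angstrom^3; equals `2 V_e - V_c` at
#'   `q = 0`.
#' @export
dumbbell_amplitude_closed <- function(q, alpha, params) {
  stopifnot(inherits(params, "dumbbell_params"))
  V_e <- 4 / 3 * pi * params$a * params$r_eq^2
  L <- params$L_tot
  fe <- ellipsoid_amplitude(q, alpha, params$a, params$r_eq) *
    2 * cos(q * params$d * cos(alpha) / 2)
  if (params$Rh > 0) {
    V_c <- pi * params$Rh^2 * L
    fe <- V_e * fe - V_c * cylinder_amplitude(q, alpha, params$Rh, L)
  } else {
    fe <- V_e * fe
  }
  fe
}

# ---- numeric amplitude machinery --------------------------------------
#
# The dumbbell body is axially symmetric and mirror-symmetric in z, so its
# amplitude at orientation angle alpha reduces to a 2-D quadrature over the
# (r, z) quarter-plane:
#   F(q, alpha) = 4 pi int_0^Zmax int chi(r, z) J0(q sin(alpha) r)
#                               cos(q cos(alpha) z) r dr dz
# with indicator chi = [inside either ellipsoid] AND [r > Rh]. For each z
# the admissible radii form the annulus (Rh, rmax(z)], so the radial
# integral over each grid cell is taken over the covered sub-interval
# exactly in the r^2 measure, with J0 frozen at the cell midpoint; z uses
# the midpoint rule. This keeps the separable structure
#   F = 4 pi * rowSums((J0mat %*% W) * cosmat)
# where J0mat and cosmat depend only on the (q, alpha) set and the fixed
# grid, and only the weight matrix W depends on the geometry - the key to
# evaluating thousands of geometries cheaply during a swarm fit.

# Geometry weight matrix W[i, j] = dz * (c1^2 - c0^2)/2 over the covered
# radial sub-interval of cell i in the z-column j. F(0) = 4*pi*sum(W) is
# the body volume.
dumbbell_cell_weights <- function(d, a, r_eq, Rh, r_edges, z_mid, dz) {
  n_r <- length(r_edges) - 1
  u <- (z_mid - d / 2) / a
  rmax_z <- r_eq * sqrt(pmax(0, 1 - u * u))
  c1 <- outer(r_edges[-1], rmax_z, pmin)
  c0 <- matrix(pmax(r_edges[-(n_r + 1)], Rh), n_r, length(z_mid))
  pmax(c1 * c1 - c0 * c0, 0) / 2 * dz
}

# Precompute the (q, alpha) quadrature tables once; returns a closure
# evaluating F (n_q x n_alpha matrix, units A^3) for any geometry.
dumbbell_quadrature <- function(q, alpha, r_max, z_max, n_r, n_z) {
  qs <- as.vector(outer(q, sin(alpha)))
  qc <- as.vector(outer(q, cos(alpha)))
  r_edges <- seq(0, r_max, length.out = n_r + 1)
  r_mid <- (r_edges[-1] + r_edges[-(n_r + 1)]) / 2
  z_edges <- seq(0, z_max, length.out = n_z + 1)
  z_mid <- (z_edges[-1] + z_edges[-(n_z + 1)]) / 2
  dz <- z_edges[2] - z_edges[1]
  J0 <- matrix(besselJ(outer(qs, r_mid), 0), length(qs), n_r)
  Cm <- cos(outer(qc, z_mid))
  n_q <- length(q); n_alpha <- length(alpha)
  function(d, a, r_eq, Rh) {
    W <- dumbbell_cell_weights(d, a, r_eq, Rh, r_edges, z_mid, dz)
    Fq <- 4 * pi * rowSums((J0 %*% W) * Cm)
    dim(Fq) <- c(n_q, n_alpha)
    attr(Fq, "volume") <- 4 * pi * sum(W)
    Fq
  }
}

#' Numeric dumbbell amplitude (exact indicator-function quadrature)
#'
#' Reference amplitude (times volume, Angstrom^3) of the dumbbell body,
#' computed by direct quadrature of the indicator density
#' `chi(r, z) = [inside ellipsoid 1 OR ellipsoid 2] AND [r > Rh]`:
#' `F(q, alpha) = 4 pi int int chi J0(q sin(alpha) r) cos(q cos(alpha) z)
#' r dr dz`, exploiting axial and z-mirror symmetry. Unlike the closed
#' form it counts the ellipsoid overlap region once and removes only hole
#' material that actually lies inside an ellipsoid, so it is exact for the
#' overlapping geometries typical of hexamer rings.
#'
#' @inheritParams dumbbell_amplitude_closed
#' @param q momentum transfer, 1/Angstrom; vector allowed.
#' @param alpha orientation angle, radians, scalar.
#' @param grid a [dumbbell_grid()] specification.
#' @return amplitude times volume, Angstrom^3; `F(0)` equals the body
#'   volume.
#' @export
dumbbell_amplitude_numeric <- function(q, alpha, params,
                                       grid = dumbbell_grid()) {
  stopifnot(inherits(params, "dumbbell_params"), length(alpha) == 1)
  ev <- function(n_r, n_z) {
    f <- dumbbell_quadrature(q, alpha, params$r_eq, params$d / 2 + params$a,
                             n_r, n_z)
    f(params$d, params$a, params$r_eq, params$Rh)
  }
  Fq <- ev(grid$n_r, grid$n_z)
  if (isTRUE(grid$check)) {
    Fc <- ev(max(16L, grid$n_r %/% 2L), max(16L, grid$n_z %/% 2L))
    scale <- max(abs(attr(Fq, "volume")), 1e-12)
    err <- max(abs(Fq - Fc)) / scale
    if (err > grid$tol)
      stop(sprintf(paste0("numeric amplitude failed self-convergence: ",
                          "refinement changes F by %.2e (tol %.1e); ",
                          "increase n_r/n_z"), err, grid$tol))
  }
  v <- as.vector(Fq)
  attr(v, "volume") <- attr(Fq, "volume")
  v
}

#' Quadrature grid specification for the numeric dumbbell amplitude
#'
#' @param n_r,n_z number of radial / axial cells over the quarter
#'   cross-section `[0, r_eq] x [0, d/2 + a]`.
#' @param check run a half-resolution self-convergence check and fail with
#'   a diagnostic when the grid is too coarse.
#' @param tol relative tolerance (against the body volume scale) for the
#'   self-convergence check.
#' @return a list with class `dumbbell_grid`.
#' @export
dumbbell_grid <- function(n_r = 256L, n_z = 256L, check = TRUE, tol = 1e-3) {
  if (n_r < 16 || n_z < 16) stop("grid must have at least 16x16 cells")
  structure(list(n_r = as.integer(n_r), n_z = as.integer(n_z),
                 check = check, tol = tol), class = "dumbbell_grid")
}

#' Orientational average of a squared amplitude
#'
#' Averages `|F(q, alpha)|^2` over particle orientations for an axially
#' symmetric body:
#' `<|F|^2>(q) = int_0^{pi/2} |F(q, alpha)|^2 sin(alpha) d(alpha)`,
#' by Gauss-Legendre quadrature in `alpha`. A convergence check doubles the
#' node count and fails with a diagnostic when the two results differ by
#' more than `tol` relative.
#'
#' @param amplitude_fn function `(q, alpha)` returning the amplitude,
#'   vectorised over `alpha` for scalar `q`.
#' @param q momentum transfer vector, 1/Angstrom.
#' @param n_nodes number of Gauss-Legendre nodes (>= 16).
#' @param check verify stability under node doubling.
#' @param tol relative tolerance of the doubling check.
#' @return vector `<|F|^2>(q)`.
#' @export
orientational_average <- function(amplitude_fn, q, n_nodes = 76L,
                                  check = TRUE, tol = 1e-4) {
  if (n_nodes < 16) stop("n_nodes must be >= 16")
  avg <- function(n) {
    gl <- gl_nodes(n, 0, pi / 2)
    w <- gl$w * sin(gl$x)
    vapply(q, function(qi)
      sum(w * amplitude_fn(qi, gl$x)^2), numeric(1))
  }
  s1 <- avg(n_nodes)
  if (check) {
    s2 <- avg(2L * n_nodes)
    rel <- abs(s1 - s2) / pmax(abs(s2), max(abs(s2)) * 1e-12)
    if (max(rel) > tol)
      stop(sprintf(paste0("orientational average not converged at %d ",
                          "nodes: node doubling changes it by %.2e ",
                          "(tol %.1e)"), n_nodes, max(rel), tol))
    s1 <- s2
  }
  s1
}

#' Dumbbell model intensity curve
#'
#' Orientationally averaged 1-D intensity of the dumbbell model:
#' `I(Q) = scale * <|F|^2>(Q) / <|F(0)|^2> + A_up * Q^-p + background`.
#' With no upturn (`A_up = 0`), `I(Q -> 0) = scale + background`, i.e. the
#' scale parameter is the forward scattering above background.
#'
#' The default `method = "numeric"` uses the exact indicator-function
#' amplitude. `method = "closed"` uses the fast superposition closed form;
#' when the two ellipsoids overlap it emits a warning and still computes,
#' since the closed form then double-counts the overlap region.
#'
#' @param Q momentum transfer grid, 1/Angstrom, strictly increasing, > 0.
#' @param params a [dumbbell_params()].
#' @param method `"numeric"` (reference) or `"closed"` (approximation).
#' @param n_alpha Gauss-Legendre orientation nodes.
#' @param n_r,n_z quadrature grid for the numeric method.
#' @return a [scattering_curve()] (with zero `sigma_i`).
#' @export
dumbbell_intensity <- function(Q, params, method = c("numeric", "closed"),
                               n_alpha = 76L, n_r = 256L, n_z = 256L) {
  stopifnot(inherits(params, "dumbbell_params"))
  method <- match.arg(method)
  gl <- gl_nodes(n_alpha, 0, pi / 2)
  w <- gl$w * sin(gl$x)
  if (method == "numeric") {
    f <- dumbbell_quadrature(Q, gl$x, params$r_eq, params$d / 2 + params$a,
                             n_r, n_z)
    Fq <- f(params$d, params$a, params$r_eq, params$Rh)
    S <- as.vector((Fq * Fq) %*% w)
    S0 <- attr(Fq, "volume")^2
  } else {
    if (params$overlap)
      warning(paste("closed-form dumbbell amplitude with overlapping",
                    "ellipsoids (2a > d): the overlap region is",
                    "double-counted; use method = 'numeric' for the exact",
                    "amplitude"))
    Fq <- outer(Q, gl$x, function(qi, al)
      dumbbell_amplitude_closed(qi, al, params))
    S <- as.vector((Fq * Fq) %*% w)
    V_e <- 4 / 3 * pi * params$a * params$r_eq^2
    S0 <- (2 * V_e - pi * params$Rh^2 * params$L_tot)^2
  }
  i <- params$scale * S / S0 + params$background
  if (params$upturn_amplitude > 0)
    i <- i + params$upturn_amplitude * Q^(-params$upturn_exponent)
  scattering_curve(Q, i, label = sprintf("dumbbell (%s)", method))
}

#' Polymer excluded-volume model intensity curve
#'
#' Form factor of a self-avoiding polymer chain with excluded-volume
#' exponent `nu = 1/m` (Benoit model), expressed through lower incomplete
#' gamma functions `g(s, U)`:
#' `U = Q^2 Rg^2 (2 nu + 1)(2 nu + 2) / 6`,
#' `P(Q) = g(1/(2 nu), U) / (nu U^(1/(2 nu)))
#'        - g(1/nu, U) / (nu U^(1/nu))`,
#' with `P(0) = 1` and high-Q asymptote proportional to `Q^-m`. The
#' returned intensity is `scale * P(Q) + background`. `m = 2` reduces
#' exactly to the Debye Gaussian-coil function.
#'
#' @param Q momentum transfer grid, 1/Angstrom.
#' @param params a [polymer_ev_params()]; `rg` is given in nm and
#'   converted to Angstrom internally.
#' @return a [scattering_curve()].
#' @export
polymer_ev_intensity <- function(Q, params) {
  stopifnot(inherits(params, "polymer_ev_params"))
  scattering_curve(Q, params$scale * polymer_ev_form(Q, params$rg, params$m) +
                     params$background,
                   label = "polymer excluded volume")
}

# Normalised excluded-volume form factor P(Q); rg in nm.
polymer_ev_form <- function(Q, rg, m) {
  if (m <= 1) stop("Porod exponent m must be > 1")
  nu <- 1 / m
  rg_A <- 10 * rg
  U <- Q^2 * rg_A^2 * (2 * nu + 1) * (2 * nu + 2) / 6
  s1 <- 1 / (2 * nu); s2 <- 1 / nu
  # lower incomplete gamma via the regularised pgamma
  lig <- function(s, x) pgamma(x, s) * gamma(s)
  P <- numeric(length(U))
  tiny <- U < 1e-10
  P[tiny] <- 1
  Ub <- U[!tiny]
  P[!tiny] <- lig(s1, Ub) / (nu * Ub^s1) - lig(s2, Ub) / (nu * Ub^s2)
  P
}
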