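# Brute-force geometry and scattering oracles.
#
# Everything here is deliberately independent of the quadrature-based model
# code: points are drawn by rejection sampling from the indicator function
# and intensities come from the Debye pair sum, so these routines validate
# the analytic/numeric amplitudes rather than re-using them.

# Draw n uniform points in the bounding cylinder (radius r_eq, half-length
# d/2 + a) and keep those inside the dumbbell indicator.
reject_sample <- function(params, n_prop) {
  r_eq <- params$r_eq
  zmax <- params$d / 2 + params$a
  r <- r_eq * sqrt(stats::runif(n_prop))
  th <- stats::runif(n_prop, 0, 2 * pi)
  z <- stats::runif(n_prop, -zmax, zmax)
  u <- (abs(z) - params$d / 2) / params$a
  keep <- r > params$Rh & u <= 1 & r^2 <= params$r_eq^2 * pmax(0, 1 - u^2)
  # note: u <= 1 is implied by the radial test except at r = 0
  cbind(x = r[keep] * cos(th[keep]), y = r[keep] * sin(th[keep]),
        z = z[keep])
}

#' Monte-Carlo point cloud of a dumbbell geometry
#'
#' Uniform rejection sampling inside the dumbbell body: proposals are drawn
#' uniformly in the bounding cylinder and accepted when they satisfy the
#' indicator (inside an ellipsoid, radial distance > Rh). Deterministic
#' given the seed.
#'
#' @param params a [dumbbell_params()].
#' @param n number of accepted points to return (>= 1).
#' @param seed integer RNG seed.
#' @return an object of class `point_cloud`: list with `xyz` (n x 3 matrix,
#'   Angstrom), `seed`, `params` and the empirical `acceptance` rate.
#' @export
sample_points <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "dumbbell_params"), n >= 1)
  with_seed(seed, {
    pts <- matrix(numeric(0), 0, 3)
    proposed <- 0
    while (nrow(pts) < n) {
      batch <- max(4L * (n - nrow(pts)), 10000L)
      pts <- rbind(pts, reject_sample(params, batch))
      proposed <- proposed + batch
      if (proposed >= 1e5 && nrow(pts) / proposed < 1e-3)
        stop(sprintf(paste0("degenerate geometry: acceptance rate %.2e ",
                            "after %g proposals"),
                     nrow(pts) / proposed, proposed))
    }
    structure(list(xyz = pts[seq_len(n), , drop = FALSE], seed = seed,
                   params = params, acceptance = nrow(pts) / proposed),
              class = "point_cloud")
  })
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("Point cloud: %d points (seed %d, acceptance %.3f)\n",
              nrow(x$xyz), x$seed, x$acceptance))
  invisible(x)
}

#' Monte-Carlo volume of a dumbbell geometry
#'
#' Bounding-cylinder volume times the acceptance fraction of uniform
#' proposals, with the binomial standard error.
#'
#' @param params a [dumbbell_params()].
#' @param n number of proposal points (>= 1e4).
#' @param seed integer RNG seed.
#' @return list with `volume` (Angstrom^3), `se`, `n`, `seed`.
#' @export
mc_volume <- function(params, n = 1e6, seed = 1L) {
  stopifnot(inherits(params, "dumbbell_params"), n >= 1e4)
  v_box <- pi * params$r_eq^2 * (params$d + 2 * params$a)
  k <- with_seed(seed, nrow(reject_sample(params, n)))
  p <- k / n
  if (p < 1e-3)
    stop(sprintf("degenerate geometry: acceptance rate %.2e", p))
  list(volume = v_box * p, se = v_box * sqrt(p * (1 - p) / n),
       n = n, seed = seed)
}

#' Monte-Carlo radius of gyration of a dumbbell geometry
#'
#' Root-mean-square distance of uniformly sampled interior points from
#' their centroid. By symmetry the centroid is at the origin; the sample
#' centroid is reported so tests can assert it vanishes within noise. The
#' standard error follows from the delta method on the mean of r^2.
#'
#' @param params a [dumbbell_params()].
#' @param n number of accepted sample points (>= 1e4).
#' @param seed integer RNG seed.
#' @return list with `rg` (Angstrom), `se`, `centroid`, `n`, `seed`.
#' @export
mc_rg <- function(params, n = 1e6, seed = 1L) {
  stopifnot(n >= 1e4)
  cloud <- sample_points(params, n, seed)
  ctr <- colMeans(cloud$xyz)
  d2 <- rowSums(sweep(cloud$xyz, 2, ctr)^2)
  m2 <- mean(d2)
  rg <- sqrt(m2)
  list(rg = rg, se = stats::sd(d2) / (2 * rg * sqrt(n)),
       centroid = ctr, n = n, seed = seed)
}

#' Debye-sum scattering intensity of a point cloud
#'
#' Exact orientationally averaged intensity of a discrete point set,
#' `I(q) = (1/N^2) sum_ij sinc(q r_ij)`, normalised so `I(0) = 1`. This is
#' the brute-force ground truth against which the quadrature-based model
#' intensities are validated.
#'
#' For clouds larger than `exact_max` points the O(N^2) pair distances are
#' accumulated into a fine histogram (bin width `dr`) and the sum is taken
#' over bin centers; the associated error is O((q dr)^2) and negligible at
#' the default 0.25 Angstrom bins for small-angle q.
#'
#' When the cloud stands in for a continuous body, the finite-N self term
#' `1/N` biases the sum upward (noticeably so wherever the form factor is
#' of order `1/N` or below); `subtract_self = TRUE` removes it,
#' returning `(I - 1/N) / (1 - 1/N)`, the unbiased pair-average.
#'
#' @param cloud a `point_cloud` from [sample_points()], or an n x 3 matrix.
#' @param Q momentum transfer grid, 1/Angstrom.
#' @param exact_max largest N for which the exact pair sum is used.
#' @param dr histogram bin width (Angstrom) beyond `exact_max`.
#' @param subtract_self remove the `1/N` self-term bias (default `FALSE`,
#'   keeping the exact point-set convention `I(0) = 1`).
#' @return a [scattering_curve()] with `I(0) = 1` normalisation (before
#'   any self-term correction).
#' @export
debye_intensity <- function(cloud, Q, exact_max = 3000L, dr = 0.25,
                            subtract_self = FALSE) {
  xyz <- if (inherits(cloud, "point_cloud")) cloud$xyz else as.matrix(cloud)
  n <- nrow(xyz)
  stopifnot(n >= 1, ncol(xyz) == 3)
  if (n > 5e4) stop("cloud too large for the O(N^2) Debye sum (N > 5e4)")
  if (n == 1)
    return(scattering_curve(Q, rep(1, length(Q)), label = "Debye sum"))
  if (n <= exact_max) {
    rij <- stats::dist(xyz)
    i <- vapply(Q, function(qi) (n + 2 * sum(sinc(qi * rij))) / n^2,
                numeric(1))
  } else {
    # chunked pair-distance histogram
    rmax <- sqrt(sum((apply(xyz, 2, max) - apply(xyz, 2, min))^2))
    nb <- ceiling(rmax / dr) + 1L
    counts <- numeric(nb)
    chunk <- max(1L, floor(2e7 / n))
    i0 <- 1L
    while (i0 < n) {
      i1 <- min(n, i0 + chunk - 1L)
      blk <- xyz[i0:i1, , drop = FALSE]
      d2 <- outer(rowSums(blk^2), rowSums(xyz^2), "+") -
        2 * tcrossprod(blk, xyz)
      d <- sqrt(pmax(d2, 0))
      # keep strictly-upper pairs: columns beyond each row's global index
      sel <- col(d) > (i0:i1)[row(d)]
      idx <- pmin(nb, 1L + as.integer(floor(d[sel] / dr)))
      counts <- counts + tabulate(idx, nbins = nb)
      i0 <- i1 + 1L
    }
    rc <- (seq_len(nb) - 0.5) * dr
    i <- vapply(Q, function(qi)
      (n + 2 * sum(counts * sinc(qi * rc))) / n^2, numeric(1))
  }
  if (subtract_self && n > 1) i <- (i - 1 / n) / (1 - 1 / n)
  scattering_curve(Q, i, label = "Debye sum")
}

#' Export a point cloud as XYZ text
#'
#' Writes the standard XYZ chemical file format with a dummy element
#' ("C") per point, for visual inspection in molecular viewers.
#'
#' @param cloud a `point_cloud`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- nrow(cloud$xyz)
  lines <- c(as.character(n),
             sprintf("dumbbell point cloud, seed %d", cloud$seed),
             sprintf("C %12.4f %12.4f %12.4f",
                     cloud$xyz[, 1], cloud$xyz[, 2], cloud$xyz[, 3]))
  writeLines(lines, path)
  invisible(path)
}
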