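#' Numerically stable sinc
#'
#' Computes sin(x)/x with a series expansion near zero, where the naive
#' ratio loses precision. Used throughout the Debye sum and the cylinder
#' amplitude.
#'
#' @param x numeric vector (radians; dimensionless products q*r).
#' @return sin(x)/x, with sinc(0) = 1.
#' @export
sinc <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  xs <- x[small]
  out[small] <- 1 - xs^2 / 6 + xs^4 / 120
  out[!small] <- sin(x[!small]) / x[!small]
  out
}

# Run code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Gauss-Legendre nodes/weights on [a, b].
gl_nodes <- function(n, a, b) {
  gl <- pracma::gaussLegendre(n, a, b)
  list(x = gl$x, w = gl$w)
}

# 2*J1(x)/x, stable at x = 0.
besinc <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-5
  xs <- x[small]
  out[small] <- 1 - xs^2 / 8
  xb <- x[!small]
  out[!small] <- 2 * besselJ(abs(xb), 1) / abs(xb)
  out
}
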