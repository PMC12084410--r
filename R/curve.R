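#' Reduced 1-D scattering curve
#'
#' Container for a reduced small-angle scattering curve: momentum transfer
#' `q` (inverse Angstrom), intensity `i`, intensity uncertainty `sigma_i`
#' and, optionally, the per-point q resolution `sigma_q` used for
#' instrumental smearing.
#'
#' @param q numeric vector of momentum transfer, strictly increasing, all
#'   > 0, in 1/Angstrom.
#' @param i intensity, same length as `q`, finite.
#' @param sigma_i intensity uncertainties, >= 0. Defaults to zero
#'   (noise-free model curve).
#' @param sigma_q optional per-point Gaussian q-resolution widths, >= 0.
#' @param label free-text label carried through analyses and reports.
#' @param metadata optional named list recorded with the curve (generation
#'   parameters, provenance); written as header lines by
#'   [write_sans_curve()].
#' @return an object of class `scattering_curve`.
#' @export
scattering_curve <- function(q, i, sigma_i = NULL, sigma_q = NULL,
                             label = "", metadata = list()) {
  q <- as.numeric(q); i <- as.numeric(i)
  if (is.null(sigma_i)) sigma_i <- numeric(length(q))
  sigma_i <- as.numeric(sigma_i)
  if (length(i) != length(q) || length(sigma_i) != length(q))
    stop("q, i and sigma_i must have equal length")
  if (!is.null(sigma_q) && length(sigma_q) != length(q))
    stop("sigma_q must match the length of q")
  if (any(!is.finite(q)) || any(q <= 0)) stop("all q must be finite and > 0")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  if (any(!is.finite(i))) stop("intensities must be finite")
  if (any(sigma_i < 0)) stop("sigma_i must be >= 0")
  if (!is.null(sigma_q) && any(sigma_q < 0)) stop("sigma_q must be >= 0")
  structure(list(q = q, i = i, sigma_i = sigma_i, sigma_q = sigma_q,
                 label = label, metadata = metadata),
            class = "scattering_curve")
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("Scattering curve%s: %d points, Q in [%.4g, %.4g] 1/A\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$q), min(x$q), max(x$q)))
  cat(sprintf("  I(Qmin) = %.4g, I(Qmax) = %.4g, %s sigma_I, %s sigma_Q\n",
              x$i[1], x$i[length(x$i)],
              if (any(x$sigma_i > 0)) "with" else "zero",
              if (is.null(x$sigma_q)) "no" else "with"))
  invisible(x)
}

#' @export
as.data.frame.scattering_curve <- function(x, ...) {
  df <- data.frame(q = x$q, i = x$i, sigma_i = x$sigma_i)
  if (!is.null(x$sigma_q)) df$sigma_q <- x$sigma_q
  df
}

#' Write a reduced scattering curve as ASCII columns
#'
#' Writes the de-facto standard reduced small-angle-scattering text format:
#' `#`-prefixed header lines (`# key: value`) carrying the curve label and
#' any metadata, followed by 3 or 4 whitespace-separated columns
#' Q (1/Angstrom), I, sigma_I and, when present, sigma_Q. Values are
#' written with 17 significant digits so a write/read round trip is
#' bit-exact.
#'
#' @param curve a [scattering_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sans_curve <- function(curve, path) {
  stopifnot(inherits(curve, "scattering_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c(list(label = curve$label), curve$metadata)
  for (k in names(hdr)) {
    v <- hdr[[k]]
    writeLines(sprintf("# %s: %s", k,
                       paste(formatC(v, digits = 17, format = "g"),
                             collapse = " ")), con)
  }
  writeLines(sprintf("# columns: %s", if (is.null(curve$sigma_q))
    "Q I sigma_I" else "Q I sigma_I sigma_Q"), con)
  df <- as.data.frame(curve)
  writeLines(apply(df, 1, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = " ")), con)
  invisible(path)
}

#' Read a reduced scattering curve from ASCII columns
#'
#' Parses the format written by [write_sans_curve()] (and typical reduced
#' SANS/SAXS exports): `#` header lines followed by 3 or 4 numeric columns.
#' Malformed data lines raise an error naming the offending line number.
#'
#' @param path input file path.
#' @return a [scattering_curve()] with header metadata attached.
#' @export
read_sans_curve <- function(path) {
  lines <- readLines(path)
  is_hdr <- grepl("^\\s*#", lines)
  meta <- list()
  for (h in lines[is_hdr]) {
    m <- regmatches(h, regexec("^\\s*#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
      meta[[trimws(m[2])]] <- if (anyNA(vals)) trimws(m[3]) else vals
    }
  }
  data_idx <- which(!is_hdr & nzchar(trimws(lines)))
  if (length(data_idx) == 0) stop("no data lines in ", path)
  rows <- lapply(data_idx, function(j) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[j]), "\\s+")[[1]]))
    if (length(v) < 3 || length(v) > 4 || anyNA(v))
      stop(sprintf("malformed data line %d in %s: '%s'", j, path, lines[j]))
    v
  })
  ncol <- unique(vapply(rows, length, 1L))
  if (length(ncol) != 1)
    stop("inconsistent column counts in ", path)
  mat <- do.call(rbind, rows)
  label <- if (is.character(meta$label)) meta$label else ""
  meta$label <- NULL
  scattering_curve(q = mat[, 1], i = mat[, 2], sigma_i = mat[, 3],
                   sigma_q = if (ncol == 4) mat[, 4] else NULL,
                   label = label, metadata = meta)
}

#' Restrict a curve to a Q window
#'
#' Subsets a curve to `qmin <= Q <= qmax`, e.g. to truncate the low-Q
#' cluster-upturn region before fitting a single-particle model instead of
#' fitting the upturn power law jointly.
#'
#' @param curve a [scattering_curve()].
#' @param qmin,qmax window limits in 1/Angstrom.
#' @return the restricted [scattering_curve()].
#' @export
trim_curve <- function(curve, qmin = -Inf, qmax = Inf) {
  stopifnot(inherits(curve, "scattering_curve"))
  keep <- curve$q >= qmin & curve$q <= qmax
  if (sum(keep) < 2) stop("fewer than 2 points left in the Q window")
  scattering_curve(curve$q[keep], curve$i[keep], curve$sigma_i[keep],
                   if (!is.null(curve$sigma_q)) curve$sigma_q[keep],
                   label = curve$label, metadata = curve$metadata)
}
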