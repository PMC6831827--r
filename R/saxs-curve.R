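#' SAXS curve container
#'
#' A `saxs_curve` is a tibble with columns `q` (scattering vector,
#' inverse Angstrom, strictly increasing), `I` (intensity, arbitrary units)
#' and optionally `sigma` (per-point uncertainty, > 0). All SAXS math in the
#' package consumes and produces this container.
#'
#' @param q,I,sigma Numeric vectors (sigma optional).
#' @param metadata Optional named list stored as an attribute.
#' @return A `saxs_curve` tibble.
#' @export
saxs_curve <- function(q, I, sigma = NULL, metadata = list()) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) abort("q and I must have equal length")
  if (any(diff(q) <= 0)) abort("q must be strictly increasing")
  if (any(q < 0)) abort("q must be non-negative")
  df <- tibble(q = q, I = I)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) abort("sigma must match q in length")
    if (any(sigma <= 0)) abort("sigma must be positive where present")
    df$sigma <- sigma
  }
  class(df) <- c("saxs_curve", class(tibble()))
  attr(df, "metadata") <- metadata
  df
}

has_sigma <- function(curve) "sigma" %in% names(curve)

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("<saxs_curve> %d points, q %.4g-%.4g A^-1%s\n", nrow(x),
              min(x$q), max(x$q),
              if (has_sigma(x)) ", with uncertainties" else ""))
  NextMethod()
}

#' Read a 3-column ASCII SAXS curve
#'
#' Whitespace-separated `q I sigma` records with `#` comment lines, the
#' dialect used by SASBDB/ATSAS-style `.dat` files. A two-column file is
#' accepted (no uncertainties).
#'
#' @param path File path.
#' @param q_unit `"A^-1"` (default) or `"nm^-1"`; nm^-1 input is converted
#'   to inverse Angstrom.
#' @return A [saxs_curve()].
#' @export
read_saxs <- function(path, q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("q", "I", "sigma")[1:3], fill = TRUE)
  tab <- tab[stats::complete.cases(tab[, 1:2]), , drop = FALSE]
  if (nrow(tab) == 0) abort(sprintf("no data rows in %s", path))
  q <- tab$q
  if (q_unit == "nm^-1") q <- q / 10
  sigma <- if (ncol(tab) >= 3 && !all(is.na(tab$sigma))) tab$sigma else NULL
  keep <- q > 0
  saxs_curve(q[keep], tab$I[keep],
             if (!is.null(sigma)) sigma[keep],
             metadata = list(source = path, q_unit = "A^-1"))
}

#' Write a curve as 3-column ASCII
#'
#' @param curve A [saxs_curve()].
#' @param path Output path.
#' @param comment Optional comment line written after the header.
#' @return `path`, invisibly.
#' @export
write_saxs <- function(curve, path, comment = NULL) {
  hdr <- c("# q(A^-1) I sigma", comment)
  sig <- if (has_sigma(curve)) curve$sigma else rep(NA_real_, nrow(curve))
  body <- sprintf("%.6e %.6e %.6e", curve$q, curve$I, sig)
  if (!has_sigma(curve)) body <- sprintf("%.6e %.6e", curve$q, curve$I)
  writeLines(c(hdr, body), path)
  invisible(path)
}
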