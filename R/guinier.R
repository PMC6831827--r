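#' Guinier analysis of a SAXS curve
#'
#' Weighted linear regression of `ln I` against `q^2` in the low-angle
#' regime, where `I(q) ~ I0 exp(-q^2 Rg^2 / 3)`. Either a fixed `q` window
#' is given, or the automatic policy is used: start from the lowest valid
#' `q`, extend the window while `q Rg <= qrg_max` (default 1.3) and the fit
#' stays linear (`r^2 >= r2_min`), iterating the Rg estimate to convergence
#' (0.1 A tolerance, at most 20 iterations).
#'
#' For strongly elongated particles the Guinier window curves downward and
#' the fitted Rg underestimates the true radius of gyration by several
#' percent even at `q Rg <= 1`; the pair-distribution route ([ift_pr()])
#' does not share this bias.
#'
#' @param curve A [saxs_curve()]; uncertainties are used as weights when
#'   present.
#' @param qmin,qmax Optional fixed fit window (inverse Angstrom).
#' @param qrg_max Automatic-policy upper bound on `q Rg`.
#' @param r2_min Minimum linearity retained by the automatic policy.
#' @param min_points Minimum number of points in the window.
#' @return A `guinier_fit` object with fields `rg`, `i0`, `qmin`, `qmax`,
#'   `qrg_max` (at the window edge), `r2`, `n`.
#' @export
#' @examples
#' q <- seq(0.008, 0.05, length.out = 60)
#' g <- guinier_fit(saxs_curve(q, 100 * exp(-q^2 * 20^2 / 3)))
#' g$rg
guinier_fit <- function(curve, qmin = NULL, qmax = NULL, qrg_max = 1.3,
                        r2_min = 0.99, min_points = 5) {
  stopifnot(inherits(curve, "saxs_curve"))
  fixed <- !is.null(qmin) || !is.null(qmax)
  if (is.null(qmin)) qmin <- min(curve$q)
  fit_window <- function(qlo, qhi) {
    sel <- curve$q >= qlo & curve$q <= qhi
    n <- sum(sel)
    if (n < min_points) {
      abort(sprintf("Guinier window [%g, %g] holds %d points (< %d)",
                    qlo, qhi, n, min_points))
    }
    qi <- curve$q[sel]; Ii <- curve$I[sel]
    if (any(Ii <= 0)) abort("non-positive intensities inside the Guinier window")
    w <- if (has_sigma(curve)) (Ii / curve$sigma[sel])^2 else rep(1, n)
    ft <- lm(log(Ii) ~ I(qi^2), weights = w)
    sl <- coef(ft)[[2]]
    if (sl >= 0) abort("Guinier window has non-negative slope; no Rg")
    list(rg = sqrt(-3 * sl), i0 = exp(coef(ft)[[1]]),
         r2 = summary(ft)$r.squared, n = n, qlo = min(qi), qhi = max(qi))
  }
  if (fixed) {
    if (is.null(qmax)) qmax <- max(curve$q)
    res <- fit_window(qmin, qmax)
  } else {
    qhi <- sort(curve$q[curve$q >= qmin])[min_points]
    res <- fit_window(qmin, qhi)
    for (it in seq_len(20)) {
      qhi_new <- qrg_max / res$rg
      cand <- tryCatch(fit_window(qmin, qhi_new), error = function(e) NULL)
      if (is.null(cand)) break
      if (cand$r2 < r2_min && cand$n > min_points) {
        # retreat until linear again
        qs <- curve$q[curve$q >= qmin & curve$q <= qhi_new]
        while (length(qs) > min_points && cand$r2 < r2_min) {
          qs <- qs[-length(qs)]
          cand <- fit_window(qmin, qs[length(qs)])
        }
      }
      conv <- abs(cand$rg - res$rg) < 0.1
      res <- cand
      if (conv) break
    }
  }
  structure(list(rg = res$rg, i0 = res$i0, qmin = res$qlo, qmax = res$qhi,
                 qrg_max = res$qhi * res$rg, r2 = res$r2, n = res$n,
                 policy = if (fixed) "fixed" else "auto"),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat(sprintf("<guinier_fit> Rg %.2f A, I0 %.4g (q %.4g-%.4g, qRg %.2f, r2 %.4f, n %d)\n",
              x$rg, x$i0, x$qmin, x$qmax, x$qrg_max, x$r2, x$n))
  invisible(x)
}

#' Dimensionless Kratky transform
#'
#' Computes `(q Rg)^2 I(q) / I0` against `q Rg` and locates the global
#' maximum at `q Rg <= cutoff`. For a pure Guinier-law curve the peak sits
#' at `(sqrt(3), 3/e)`, the reference point for a compact single-domain
#' particle; elongated particles peak later and higher.
#'
#' @param curve A [saxs_curve()].
#' @param rg,i0 Radius of gyration and forward intensity; when `NULL` an
#'   automatic [guinier_fit()] supplies them.
#' @param cutoff Peak search bound on `q Rg`.
#' @return A `kratky_curve` tibble with columns `qrg`, `y`, and attributes
#'   `peak` (list with `qrg`, `height`) plus the `rg`/`i0` used.
#' @export
dimensionless_kratky <- function(curve, rg = NULL, i0 = NULL, cutoff = 10) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (is.null(rg) || is.null(i0)) {
    g <- guinier_fit(curve)
    if (is.null(rg)) rg <- g$rg
    if (is.null(i0)) i0 <- g$i0
  }
  if (rg <= 0 || i0 <= 0) abort("rg and i0 must be positive")
  x <- curve$q * rg
  y <- x^2 * curve$I / i0
  out <- tibble(qrg = x, y = y)
  class(out) <- c("kratky_curve", class(tibble()))
  inside <- x <= cutoff
  pk <- which.max(y[inside])
  attr(out, "peak") <- list(qrg = x[inside][pk], height = y[inside][pk])
  attr(out, "rg") <- rg
  attr(out, "i0") <- i0
  out
}

#' Peak of a dimensionless Kratky curve
#' @param k A `kratky_curve` from [dimensionless_kratky()].
#' @return List with `qrg` and `height`.
#' @export
kratky_peak <- function(k) attr(k, "peak")
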