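#' Pair-distance distribution from coordinates
#'
#' Weighted pair-distance histogram of the model's centers. With a positive
#' `smear` width each center is treated as a Gaussian density of that
#' standard deviation (default: the radius-of-gyration width of the
#' mean-residue-volume sphere), which turns the discrete distance spectrum
#' of a C-alpha trace into the smooth P(r) a continuous particle would
#' show; `smear = 0` gives the raw histogram.
#'
#' @param m A `protein_model` with at least two centers.
#' @param bin_width Histogram/grid spacing in Angstrom (<= 1).
#' @param weights Per-center weights (default average residue masses).
#' @param smear Gaussian center width in Angstrom (0 for none).
#' @return A `pair_distribution` tibble with columns `r`, `p` and
#'   attributes `dmax`, `rg`, `mode_r`, `self_weight`.
#' @export
pr_from_structure <- function(m, bin_width = 1, weights = NULL,
                              smear = sqrt(3 / 5) * default_residue_radius()) {
  stopifnot(inherits(m, "protein_model"))
  if (nrow(m) < 2) abort("pr_from_structure needs at least 2 centers")
  if (bin_width > 1) abort("bin_width must be <= 1 A")
  if (is.null(weights)) weights <- residue_weights(m)
  dij <- as.numeric(dist(model_xyz(m)))
  pw <- 2 * as.numeric(dist_pair_weights(weights))
  dmax <- max(dij)
  if (smear > 0) {
    r <- seq(0, dmax, by = bin_width)
    if (r[length(r)] < dmax) r <- c(r, dmax)
    sp <- sqrt(2) * smear
    p <- vapply(r, function(rr) {
      if (rr <= 0) return(0)
      sum(pw * rr / (dij * sp * sqrt(2 * pi)) *
            (exp(-(rr - dij)^2 / (2 * sp^2)) - exp(-(rr + dij)^2 / (2 * sp^2))))
    }, numeric(1))
    p[1] <- 0
    p[length(p)] <- 0
  } else {
    # histogram over distance bins; each occupied bin is represented by its
    # weight-averaged distance so the forward transform stays first-order
    # exact, with zero boundary points at r = 0 and just past Dmax
    nb <- ceiling(dmax / bin_width) + 1L
    bin <- pmin(pmax(ceiling(dij / bin_width), 1L), nb)
    wb <- rowsum_by(pw, bin, nb)
    rb <- rowsum_by(pw * dij, bin, nb)
    keep <- wb != 0
    r <- c(0, rb[keep] / wb[keep], dmax + bin_width)
    p <- c(0, wb[keep] / bin_width, 0)
    return(new_pair_distribution(r, p, dmax = dmax,
                                 self_weight = sum(weights^2),
                                 extra = list(dr = c(0, rep(bin_width, sum(keep)), 0))))
  }
  new_pair_distribution(r, p, dmax = dmax, self_weight = sum(weights^2))
}

new_pair_distribution <- function(r, p, dmax, self_weight = 0, extra = list()) {
  out <- tibble(r = r, p = p)
  class(out) <- c("pair_distribution", class(tibble()))
  attr(out, "dmax") <- dmax
  attr(out, "self_weight") <- self_weight
  tot <- sum(p)
  attr(out, "rg") <- if (tot > 0) sqrt(sum(r^2 * p) / (2 * tot)) else NA_real_
  attr(out, "mode_r") <- r[which.max(p)]
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  out
}

#' @export
print.pair_distribution <- function(x, ...) {
  cat(sprintf("<pair_distribution> Dmax %.1f A, Rg %.2f A, mode %.1f A, %d points\n",
              attr(x, "dmax"), attr(x, "rg"), attr(x, "mode_r"), nrow(x)))
  invisible(x)
}

#' Dmax, Rg and mode of a pair distribution
#' @param pr A `pair_distribution`.
#' @return Named list with `dmax`, `rg`, `mode_r`.
#' @export
pr_summary <- function(pr) {
  list(dmax = attr(pr, "dmax"), rg = attr(pr, "rg"),
       mode_r = attr(pr, "mode_r"))
}

#' Forward scattering transform of a pair distribution
#'
#' `I(q) = self + integral p(r) sinc(q r) dr`, the reciprocal-space
#' counterpart of [pr_from_structure()] (the self term is zero for P(r)
#' obtained from data).
#'
#' @param pr A `pair_distribution`.
#' @param q Scattering-vector grid.
#' @return A [saxs_curve()].
#' @export
pr_to_saxs <- function(pr, q) {
  r <- pr$r; p <- pr$p
  self <- attr(pr, "self_weight")
  if (is.null(self)) self <- 0
  # histogram-type distributions carry explicit per-point bin widths;
  # smooth ones integrate by trapezoid
  w_int <- attr(pr, "dr")
  if (is.null(w_int)) {
    dr <- diff(r)
    w_int <- c(dr[1] / 2, (dr[-1] + dr[-length(dr)]) / 2,
               dr[length(dr)] / 2)
  }
  I <- vapply(q, function(qq) {
    s <- if (qq == 0) rep(1, length(r)) else {
      out <- rep(1, length(r)); nz <- r > 0
      out[nz] <- sin(qq * r[nz]) / (qq * r[nz]); out
    }
    self + sum(p * s * w_int)
  }, numeric(1))
  saxs_curve(q, I, metadata = list(source = "pr_to_saxs"))
}

#' Indirect Fourier transform: P(r) from a measured curve
#'
#' Solves for a non-negative P(r) on `n_r` grid points over `[0, dmax]`
#' with `p(0) = p(dmax) = 0`, minimizing the sigma-weighted residual to the
#' data plus a curvature (second-difference) penalty `alpha`. When `alpha`
#' is `NULL` a multiplicative sweep is run and the largest `alpha` whose
#' chi-square stays within 10% of the best is kept (the smoothest solution
#' compatible with the data).
#'
#' @param curve A [saxs_curve()] with uncertainties.
#' @param dmax Assumed maximum dimension (Angstrom).
#' @param alpha Smoothness weight, or `NULL` for the automatic sweep.
#' @param n_r Number of r-grid points (default 101).
#' @return A `pair_distribution` with extra attributes `chi2`, `alpha` and
#'   `fit` (the fitted curve as a [saxs_curve()]).
#' @export
ift_pr <- function(curve, dmax, alpha = NULL, n_r = 101) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (!has_sigma(curve)) abort("ift_pr needs a curve with uncertainties")
  if (dmax <= 0) abort("dmax must be positive")
  # normalize intensities so the optimizer works near unit scale
  iscale <- max(abs(curve$I))
  q <- curve$q; I <- curve$I / iscale; sig <- curve$sigma / iscale
  r <- seq(0, dmax, length.out = n_r)
  dr <- r[2] - r[1]
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  A <- outer(q, r, function(qq, rr) sinc(qq * rr)) * dr
  # trapezoid end-weights; end points are pinned to zero anyway
  A[, 1] <- A[, 1] / 2; A[, n_r] <- A[, n_r] / 2
  free <- 2:(n_r - 1)
  Af <- A[, free, drop = FALSE]
  W2 <- 1 / sig^2
  # second-difference operator on the full grid (zeros at the ends included)
  D <- diff(diag(n_r), differences = 2)
  Df <- D[, free, drop = FALSE]
  DtD <- crossprod(Df)
  AtW2 <- t(Af * W2)
  AtA <- AtW2 %*% Af
  Atb <- AtW2 %*% I
  nfree <- length(free)
  # smooth positive start: scaled beta-like bump
  p0 <- (r[free] / dmax)^2 * (1 - r[free] / dmax)
  s0 <- sum(Atb * p0) / max(sum(p0 * (AtA %*% p0)), 1e-300)
  p0 <- pmax(p0 * abs(s0), 0)
  solve_alpha <- function(a) {
    fn <- function(p) {
      res <- Af %*% p - I
      sum(W2 * res^2) + a * sum((Df %*% p)^2)
    }
    gr <- function(p) {
      2 * (AtA %*% p - Atb) + 2 * a * (DtD %*% p)
    }
    opt <- optim(p0, fn, gr, method = "L-BFGS-B", lower = rep(0, nfree),
                 control = list(maxit = 2000, factr = 1e7))
    chi2 <- sum(W2 * (Af %*% opt$par - I)^2) / (length(q) - 1)
    list(p = opt$par, chi2 = chi2)
  }
  # natural scale for alpha: balance the two terms at the start
  a0 <- sum(W2 * (Af %*% p0 - I)^2) / max(sum((Df %*% p0)^2), 1e-300)
  if (is.null(alpha)) {
    alphas <- a0 * 10^seq(-6, 2, by = 1)
    sols <- lapply(alphas, solve_alpha)
    chis <- vapply(sols, function(s) s$chi2, numeric(1))
    ok <- chis <= 1.1 * min(chis)
    pick <- max(which(ok))
    sol <- sols[[pick]]
    alpha <- alphas[pick]
  } else {
    sol <- solve_alpha(alpha)
  }
  p <- numeric(n_r)
  p[free] <- sol$p * iscale
  fit <- saxs_curve(q, as.numeric(Af %*% sol$p) * iscale)
  out <- new_pair_distribution(r, p, dmax = dmax, self_weight = 0,
                               extra = list(chi2 = sol$chi2, alpha = alpha,
                                            fit = fit))
  tail_mass <- sum(p[r > 0.9 * dmax]) / max(sum(p), 1e-300)
  if (sol$chi2 > 2 && tail_mass > 0.05) {
    warn(sprintf(paste0("ift_pr: poor fit (chi2 %.2f) with P(r) piling up at",
                        " Dmax; Dmax = %.0f A is probably too small"),
                 sol$chi2, dmax))
  }
  out
}
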