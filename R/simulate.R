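#' Instrument-like measurement grid
#'
#' Linear q-grid approximating a SWING-type SEC-SAXS configuration (12 keV,
#' 1.5 m sample-detector distance): q from 0.008 to 0.5 inverse Angstrom.
#' The detector-geometry conversion is available through
#' [q_from_geometry()]; the defaults are the stated bounds.
#'
#' @param q_min,q_max Grid bounds (inverse Angstrom).
#' @param n_points Number of points (>= 50).
#' @return An `instrument_setup` list with the q grid.
#' @export
instrument_setup <- function(q_min = 0.008, q_max = 0.5, n_points = 500) {
  stopifnot(q_min >= 0, q_min < q_max, n_points >= 50)
  structure(list(q_min = q_min, q_max = q_max, n_points = as.integer(n_points),
                 q = seq(q_min, q_max, length.out = n_points)),
            class = "instrument_setup")
}

#' Scattering vector reachable by a detector geometry
#'
#' `q = 4 pi sin(theta) / lambda` with `tan(2 theta) = r / L` for a radial
#' detector position `r` at distance `L` and photon energy `energy_kev`.
#'
#' @param radius_mm Radial detector coordinate(s), mm.
#' @param distance_m Sample-detector distance, m.
#' @param energy_kev Photon energy, keV.
#' @return q in inverse Angstrom.
#' @export
q_from_geometry <- function(radius_mm, distance_m = 1.5, energy_kev = 12) {
  lambda_a <- 12.398419 / energy_kev
  theta <- atan(radius_mm / 1000 / distance_m) / 2
  4 * pi * sin(theta) / lambda_a
}

#' Counting-statistics noise model
#'
#' Per-point uncertainty `sigma(q) = sqrt((k sqrt(I))^2 + (floor I)^2)`
#' where `k` is set so that the signal-to-noise ratio of the counting term
#' equals `snr` at the first grid point, plus a relative floor. Noise draws
#' are Gaussian and independent between points.
#'
#' @param snr Target signal-to-noise at `q_min` (default 100).
#' @param floor_frac Relative uncertainty floor (default 0.01).
#' @return A `noise_model` list.
#' @export
noise_model <- function(snr = 100, floor_frac = 0.01) {
  stopifnot(snr > 0, floor_frac >= 0)
  structure(list(snr = snr, floor_frac = floor_frac), class = "noise_model")
}

#' Simulate a beamline-like SAXS curve from a model
#'
#' Evaluates the Debye intensity of the model on the instrument grid (with
#' the residue-sphere form factor by default), scales it, attaches the
#' noise model's uncertainties and optionally adds Gaussian noise.
#' Reproducible given `seed`.
#'
#' @param m A `protein_model`.
#' @param setup An [instrument_setup()].
#' @param noise A [noise_model()].
#' @param i0_scale Multiplicative intensity scale.
#' @param seed Integer seed for the noise draw (`NULL` leaves the RNG
#'   state alone).
#' @param add_noise Set `FALSE` for a noise-free curve that still carries
#'   the sigma column.
#' @param ... Passed to [debye_intensity()] (weights, form factor, method).
#' @param form_factor Residue form factor (default `"sphere"`).
#' @return A [saxs_curve()] with uncertainties; the generating parameters
#'   are recorded in the metadata.
#' @export
simulate_curve <- function(m, setup = instrument_setup(),
                           noise = noise_model(), i0_scale = 1,
                           seed = NULL, add_noise = TRUE,
                           form_factor = "sphere", ...) {
  stopifnot(inherits(setup, "instrument_setup"),
            inherits(noise, "noise_model"))
  ideal <- debye_intensity(m, setup$q, form_factor = form_factor, ...)
  I <- ideal$I * i0_scale
  k <- sqrt(I[1]) / noise$snr
  sigma <- sqrt((k * sqrt(pmax(I, 0)))^2 + (noise$floor_frac * I)^2)
  if (any(sigma <= 0)) abort("noise model produced non-positive sigma")
  Iobs <- I
  if (add_noise) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
      set.seed(seed)
    }
    Iobs <- I + rnorm(length(I), 0, sigma)
  }
  saxs_curve(setup$q, Iobs, sigma, metadata = list(
    source = "simulate_curve", seed = seed, snr = noise$snr,
    floor_frac = noise$floor_frac, i0_scale = i0_scale,
    ideal_I = I, form_factor = form_factor))
}
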