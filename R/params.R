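#' Convert ordinary frequency to angular frequency
#'
#' All internal quantities in nanonmr are angular (rad/s). Values quoted in
#' ordinary Hz -- including signal amplitudes, which have units of angular
#' frequency -- are converted on ingestion with this helper, uniformly:
#' `hz_to_rad(250)` is the carrier of a 250 Hz signal and `hz_to_rad(12500)`
#' the amplitude quoted as 12.5 kHz.
#'
#' @param hz frequency (or amplitude) in ordinary Hz.
#' @return the same quantity in rad/s.
#' @seealso [rad_to_hz()]
#' @export
#' @examples
#' hz_to_rad(250)      # 2*pi*250
#' rad_to_hz(10)       # 10/(2*pi)
hz_to_rad <- function(hz) 2 * pi * hz

#' @rdname hz_to_rad
#' @param rad angular frequency in rad/s.
#' @export
rad_to_hz <- function(rad) rad / (2 * pi)

#' Single-frequency signal hypothesis
#'
#' Parameters of one oscillating magnetic signal `g * cos(omega * t + phi)`
#' coupled to the probe spin, interrogated in repeated
#' initialize-evolve-measure cycles of duration `dt`.
#'
#' @param g signal amplitude, rad/s (angular units). Must be >= 0.
#' @param omega signal frequency, rad/s. Must be > 0.
#' @param phi signal phase, rad; normalized into `[0, 2*pi)`. In most
#'   experiments the phase is unknown and redrawn uniformly per trace; see
#'   [simulate_trace()].
#' @param dt interrogation interval, s. Must be > 0.
#' @param n_meas number of repetitions (bits per trace). Must be >= 1.
#' @return an object of class `"signal_params"`.
#' @export
#' @examples
#' signal_params(g = 10, omega = 10, dt = 0.5, n_meas = 1000)
signal_params <- function(g, omega, phi = 0, dt, n_meas) {
  stopifnot(is.numeric(g), length(g) == 1L, is.finite(g),
            is.numeric(omega), length(omega) == 1L, is.finite(omega),
            is.numeric(phi), length(phi) == 1L, is.finite(phi),
            is.numeric(dt), length(dt) == 1L, is.finite(dt),
            length(n_meas) == 1L, is.finite(n_meas))
  if (g < 0) stop("'g' must be non-negative")
  if (omega <= 0) stop("'omega' must be positive")
  if (dt <= 0) stop("'dt' must be positive")
  n_meas <- as.integer(n_meas)
  if (n_meas < 1L) stop("'n_meas' must be at least 1")
  structure(
    list(g = g, omega = omega, phi = phi %% (2 * pi), dt = dt,
         n_meas = n_meas),
    class = "signal_params"
  )
}

#' @export
print.signal_params <- function(x, ...) {
  cat(sprintf(
    "<signal_params> g = %g rad/s (%.4g Hz), omega = %g rad/s (%.4g Hz),\n",
    x$g, rad_to_hz(x$g), x$omega, rad_to_hz(x$omega)))
  cat(sprintf("  phi = %g rad, dt = %g s, n_meas = %d (T_tot = %g s)\n",
              x$phi, x$dt, x$n_meas, x$dt * x$n_meas))
  invisible(x)
}

#' Noise scenario specification
#'
#' Selects which perturbation of the ideal readout model is applied while
#' simulating a trace:
#'
#' * `"none"` -- ideal model, one uniform random (or fixed) phase per trace.
#' * `"phase_jump"` -- the random phase changes once, to a second uniform
#'   phase, at an interval index drawn uniformly over the trace.
#' * `"magnetic_jump"` -- a random magnetic offset field `db`, Normal with
#'   mean zero and standard deviation `magnetic_sigma`, adds a phase
#'   `db * dt` to each interval; `db` is redrawn once at a uniform jump
#'   index.
#' * `"amplitude_per_interval"` -- the amplitude is redrawn independently
#'   every interval from Normal(`amplitude_mean`, `amplitude_sigma`).
#' * `"mixed"` -- all three perturbations applied simultaneously.
#'
#' Parameters left as `NA` are resolved against the signal amplitude `g` at
#' simulation time using the standard study values: `magnetic_sigma = g/5`,
#' `amplitude_mean = g`, `amplitude_sigma = amplitude_mean` (relative noise
#' of one, typical of statistically polarized nano-NMR samples).
#'
#' @param variant one of `"none"`, `"phase_jump"`, `"magnetic_jump"`,
#'   `"amplitude_per_interval"`, `"mixed"`.
#' @param magnetic_sigma std. dev. of the magnetic offset, rad/s, or `NA`.
#' @param amplitude_mean mean of the per-interval amplitude, rad/s, or `NA`.
#' @param amplitude_sigma std. dev. of the per-interval amplitude, rad/s,
#'   or `NA`. Draws may be negative and are used as-is.
#' @return an object of class `"noise_spec"`.
#' @export
noise_spec <- function(variant = c("none", "phase_jump", "magnetic_jump",
                                   "amplitude_per_interval", "mixed"),
                       magnetic_sigma = NA_real_,
                       amplitude_mean = NA_real_,
                       amplitude_sigma = NA_real_) {
  variant <- match.arg(variant)
  for (v in c(magnetic_sigma, amplitude_sigma)) {
    if (!is.na(v) && v < 0) stop("noise standard deviations must be >= 0")
  }
  structure(
    list(variant = variant,
         magnetic_sigma = as.numeric(magnetic_sigma),
         amplitude_mean = as.numeric(amplitude_mean),
         amplitude_sigma = as.numeric(amplitude_sigma)),
    class = "noise_spec"
  )
}

# Fill NA noise parameters from the signal amplitude (study defaults).
resolve_noise <- function(noise, g) {
  if (is.na(noise$magnetic_sigma)) noise$magnetic_sigma <- g / 5
  if (is.na(noise$amplitude_mean)) noise$amplitude_mean <- g
  if (is.na(noise$amplitude_sigma)) noise$amplitude_sigma <- noise$amplitude_mean
  noise
}

#' @export
print.noise_spec <- function(x, ...) {
  cat(sprintf("<noise_spec> variant = %s\n", x$variant))
  if (x$variant %in% c("magnetic_jump", "mixed"))
    cat(sprintf("  magnetic_sigma = %s rad/s\n", format(x$magnetic_sigma)))
  if (x$variant %in% c("amplitude_per_interval", "mixed"))
    cat(sprintf("  amplitude ~ Normal(%s, %s) rad/s\n",
                format(x$amplitude_mean), format(x$amplitude_sigma)))
  invisible(x)
}

#' Photon-detection efficiency model
#'
#' Low photon-collection efficiency and imperfect contrast are modelled by
#' two efficiencies: the probability of registering a count given the bright
#' (`m_s = 0`) outcome, `eta_true`, and given the dark (`m_s = -1`) outcome,
#' `eta_false`. The modified success probability is
#' `Q = eta_true * P + eta_false * (1 - P)`; see [detection_probability()].
#'
#' @param eta_true true-detection efficiency in `[0, 1]`.
#' @param eta_false false-detection efficiency in `[0, eta_true]`.
#' @return an object of class `"detection_spec"`.
#' @export
#' @examples
#' detection_spec(eta_true = 0.074, eta_false = 0.7 * 0.074)
detection_spec <- function(eta_true, eta_false) {
  stopifnot(is.numeric(eta_true), length(eta_true) == 1L,
            is.numeric(eta_false), length(eta_false) == 1L)
  if (eta_true < 0 || eta_true > 1 || eta_false < 0 || eta_false > 1)
    stop("detection efficiencies must lie in [0, 1]")
  if (eta_false > eta_true)
    stop("'eta_false' must not exceed 'eta_true'")
  structure(list(eta_true = eta_true, eta_false = eta_false),
            class = "detection_spec")
}

#' @export
print.detection_spec <- function(x, ...) {
  cat(sprintf("<detection_spec> eta_true = %g, eta_false = %g\n",
              x$eta_true, x$eta_false))
  invisible(x)
}
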