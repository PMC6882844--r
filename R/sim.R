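# Core readout model: the probe accumulates the phase integral of
# g*cos(omega*t + phi) over one free-evolution interval dt, and the
# projective measurement succeeds (bit 1) with probability
#   P(t) = sin^2( (g / 2 omega) [sin(omega t + phi) - sin(omega (t - dt) + phi)]
#                 + pi/4 ).
# `g` may be a vector (per-interval amplitude noise); `db` is an additive
# magnetic offset contributing phase db*dt per interval.
p_ramsey <- function(g, omega, phi, dt, t, db = 0) {
  bracket <- (g / (2 * omega)) *
    (sin(omega * t + phi) - sin(omega * (t - dt) + phi)) + db * dt
  sin(bracket + pi / 4)^2
}

#' Success probability of a single NV measurement
#'
#' Probability of the bright outcome (bit 1) for a measurement concluding at
#' time `t`, under the single-frequency phase-accumulation model: the probe,
#' prepared along x, freely precesses under `g*cos(omega*t + phi)` for one
#' interval `dt` and is read out along y.
#'
#' @param params a [signal_params()].
#' @param t measurement time(s), s; each must be >= `params$dt`.
#' @return probability vector in `[0, 1]`, same length as `t`.
#' @export
#' @examples
#' p <- signal_params(g = 10, omega = 10, dt = 0.5, n_meas = 1000)
#' success_probability(p, t = c(0.5, 1, 1.5))
#' # zero amplitude leaves the probe on the equator: always 1/2
#' success_probability(signal_params(0, 10, 0, 0.5, 10), 0.5)
success_probability <- function(params, t) {
  stopifnot(inherits(params, "signal_params"))
  if (any(t < params$dt)) stop("'t' must be at least one interval dt")
  p_ramsey(params$g, params$omega, params$phi, params$dt, t)
}

#' Detection-efficiency-modified success probability
#'
#' Maps the ideal bright-state probability `p` through the two-efficiency
#' photon-detection model: `Q = eta_true * p + eta_false * (1 - p)`. The
#' result always lies in `[eta_false, eta_true]`, which is what limits the
#' contrast of low-collection-efficiency experiments.
#'
#' @param p ideal probability (vector allowed), in `[0, 1]`.
#' @param det a [detection_spec()].
#' @return modified probability, same length as `p`.
#' @export
#' @examples
#' detection_probability(0.5, detection_spec(0.074, 0.0518))  # 0.0629
detection_probability <- function(p, det) {
  stopifnot(inherits(det, "detection_spec"))
  if (any(p < 0 | p > 1)) stop("'p' must lie in [0, 1]")
  det$eta_true * p + det$eta_false * (1 - p)
}

# Success-probability profile over the trace's time grid for one noise
# realization. Draws all noise variates from the current RNG stream.
trace_probability <- function(params, noise, det, random_phase) {
  n <- params$n_meas
  t <- seq_len(n) * params$dt
  noise <- resolve_noise(noise, params$g)
  v <- noise$variant

  phi <- if (random_phase) stats::runif(1, 0, 2 * pi) else params$phi
  g <- params$g
  db <- 0

  if (v %in% c("phase_jump", "mixed")) {
    phi2 <- stats::runif(1, 0, 2 * pi)
    jump <- sample.int(n - 1L, 1L)
    phi <- c(rep(phi, jump), rep(phi2, n - jump))
  }
  if (v %in% c("magnetic_jump", "mixed")) {
    dbs <- stats::rnorm(2, 0, noise$magnetic_sigma)
    jump <- sample.int(n - 1L, 1L)
    db <- c(rep(dbs[1], jump), rep(dbs[2], n - jump))
  }
  if (v %in% c("amplitude_per_interval", "mixed")) {
    g <- stats::rnorm(n, noise$amplitude_mean, noise$amplitude_sigma)
  }

  p <- p_ramsey(g, params$omega, phi, params$dt, t, db)
  if (!is.null(det)) p <- detection_probability(p, det)
  p
}

#' Simulate one binary measurement trace
#'
#' Draws each bit as an independent Bernoulli with the success probability
#' of the phase-accumulation model, perturbed by the requested noise variant
#' and (optionally) passed through the detection-efficiency model.
#'
#' Noise variants (see [noise_spec()]): a phase jump redraws the uniform
#' phase once at an interval index uniform on `{1, ..., n_meas - 1}`; a
#' magnetic jump applies an additive phase `db * dt` per interval with `db ~
#' Normal(0, magnetic_sigma)` redrawn once at a uniform jump index;
#' amplitude noise redraws `g` independently every interval (draws may be
#' negative and are used as-is); `"mixed"` applies all three.
#'
#' @param params a [signal_params()].
#' @param noise a [noise_spec()]; default none.
#' @param det a [detection_spec()] or `NULL` for ideal detection.
#' @param random_phase if `TRUE` (default) the trace phase is drawn uniform
#'   on `[0, 2*pi)`, the standard experimental condition; if `FALSE`,
#'   `params$phi` is used.
#' @param label optional label stored on the trace.
#' @return an [nmr_trace()].
#' @export
#' @examples
#' set.seed(1)
#' p <- signal_params(g = 10, omega = 10, dt = 0.5, n_meas = 1000)
#' simulate_trace(p, noise_spec("phase_jump"))
simulate_trace <- function(params, noise = noise_spec("none"), det = NULL,
                           random_phase = TRUE, label = NULL) {
  stopifnot(inherits(params, "signal_params"), inherits(noise, "noise_spec"))
  if (!is.null(det)) stopifnot(inherits(det, "detection_spec"))
  p <- trace_probability(params, noise, det, random_phase)
  bits <- as.integer(stats::runif(params$n_meas) < p)
  nmr_trace(bits, params$dt, label = label)
}

# Simulate n traces under one hypothesis into a bit matrix (rows = traces).
# The noise-free model is vectorized across traces: the bracket of the
# success probability is linear in (cos phi, sin phi), so all trace
# profiles come from one matrix product.
simulate_bit_matrix <- function(n, params, noise, det, random_phase) {
  nm <- params$n_meas
  if (noise$variant == "none") {
    t <- seq_len(nm) * params$dt
    a <- params$g / (2 * params$omega)
    c1 <- a * (sin(params$omega * t) - sin(params$omega * (t - params$dt)))
    c2 <- a * (cos(params$omega * t) - cos(params$omega * (t - params$dt)))
    phis <- if (random_phase) stats::runif(n, 0, 2 * pi) else
      rep(params$phi, n)
    p <- sin(cbind(cos(phis), sin(phis)) %*% rbind(c1, c2) + pi / 4)^2
    if (!is.null(det)) p <- detection_probability(p, det)
    m <- matrix(0L, n, nm)
    m[] <- (stats::runif(n * nm) < p)
    return(m)
  }
  m <- matrix(0L, n, nm)
  for (i in seq_len(n)) {
    p <- trace_probability(params, noise, det, random_phase)
    m[i, ] <- as.integer(stats::runif(nm) < p)
  }
  m
}

#' Simulate a labelled two-hypothesis dataset
#'
#' Generates `n_per_class` traces under each of two signal hypotheses
#' (shared `dt` and length), labelled `1` and `2` in the order given. This
#' is the generator behind every discrimination experiment in the package.
#'
#' @param n_per_class traces per hypothesis.
#' @param params1,params2 [signal_params()] of the two hypotheses; must
#'   share `dt` and `n_meas`.
#' @param noise a [noise_spec()] applied to both classes.
#' @param det a [detection_spec()] or `NULL`; a list of two detection specs
#'   applies one per hypothesis.
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the dataset is bit-for-bit reproducible.
#' @param random_phase draw a fresh uniform phase per trace (default).
#' @return an [nmr_dataset()] with labels `1`/`2` and full generating
#'   metadata (including the seed).
#' @export
#' @examples
#' p1 <- signal_params(g = 10, omega = 10, dt = 0.5, n_meas = 200)
#' p2 <- signal_params(g = 10, omega = 10.05, dt = 0.5, n_meas = 200)
#' ds <- simulate_discrimination_dataset(50, p1, p2, seed = 7)
simulate_discrimination_dataset <- function(n_per_class, params1, params2,
                                            noise = noise_spec("none"),
                                            det = NULL, seed = NULL,
                                            random_phase = TRUE) {
  stopifnot(inherits(params1, "signal_params"),
            inherits(params2, "signal_params"))
  if (params1$dt != params2$dt || params1$n_meas != params2$n_meas)
    stop("the two hypotheses must share 'dt' and 'n_meas'")
  dets <- if (is.null(det) || inherits(det, "detection_spec"))
    list(det, det) else det
  stopifnot(length(dets) == 2L)
  if (!is.null(seed)) set.seed(seed)
  m1 <- simulate_bit_matrix(n_per_class, params1, noise, dets[[1]], random_phase)
  m2 <- simulate_bit_matrix(n_per_class, params2, noise, dets[[2]], random_phase)
  nmr_dataset(rbind(m1, m2), params1$dt,
              labels = rep(c(1L, 2L), each = n_per_class),
              metadata = list(params1 = unclass(params1),
                              params2 = unclass(params2),
                              noise = unclass(noise),
                              det = lapply(dets, function(d)
                                if (is.null(d)) NULL else unclass(d)),
                              seed = seed, random_phase = random_phase))
}
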