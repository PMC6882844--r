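# Shared fixture builders. All data are generated in code at test time.

# Strong-signal single-frequency configuration (g = omega = 10 rad/s,
# dt = 0.5 s) used throughout the discrimination tests.
fig_params <- function(n_meas = 1000L, omega = 10, g = 10, phi = 0) {
  signal_params(g = g, omega = omega, phi = phi, dt = 0.5, n_meas = n_meas)
}

# Low-efficiency experimental-regime configuration (scaled trace length by
# default so unit tests stay fast).
low_eff_setup <- function(n_meas = 25000L) {
  list(p1 = signal_params(hz_to_rad(12500), hz_to_rad(250), 0, 1e-5, n_meas),
       p2 = signal_params(hz_to_rad(11250), hz_to_rad(251.6), 0, 1e-5, n_meas),
       det = detection_spec(0.074, 0.7 * 0.074))
}

# Direct term-by-term Bernoulli log-likelihood oracle (independent of the
# package's batched implementation).
oracle_loglik <- function(bits, g, omega, phi, dt, det = NULL) {
  t <- seq_along(bits) * dt
  p <- sin((g / (2 * omega)) *
             (sin(omega * t + phi) - sin(omega * (t - dt) + phi)) + pi / 4)^2
  if (!is.null(det)) p <- det$eta_true * p + det$eta_false * (1 - p)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  acc <- 0
  for (j in seq_along(bits))
    acc <- acc + bits[j] * log(p[j]) + (1 - bits[j]) * log(1 - p[j])
  acc
}

# Brute-force double-loop +-1 autocorrelation oracle.
oracle_corr <- function(bits, k_max) {
  s <- ifelse(bits == 1, 1, -1)
  n <- length(s)
  vapply(seq_len(k_max), function(k) {
    acc <- 0
    for (i in seq_len(n - k)) acc <- acc + s[i] * s[i + k]
    acc / (n - k)
  }, numeric(1))
}

# All-pairs concordance (Mann-Whitney) AUC oracle, ties counted 1/2.
oracle_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  acc <- 0
  for (a in pos) for (b in neg)
    acc <- acc + (a > b) + 0.5 * (a == b)
  acc / (length(pos) * length(neg))
}
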