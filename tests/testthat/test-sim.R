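test_that("success probability matches the closed-form readout model", {
  # zero amplitude leaves the probe on the equator
  p0 <- signal_params(g = 0, omega = 7, phi = 1.3, dt = 0.5, n_meas = 10)
  expect_equal(success_probability(p0, c(0.5, 1, 2)), rep(0.5, 3))

  # full-period phase increment cancels the bracket
  pfull <- signal_params(g = 3, omega = 2 * pi / 0.5, phi = 0, dt = 0.5,
                         n_meas = 10)
  expect_equal(success_probability(pfull, (1:5) * 0.5), rep(0.5, 5),
               tolerance = 1e-12)

  # independent one-line evaluation at the strong-signal configuration
  p <- fig_params()
  direct <- sin((10 / 20) * (sin(10 * 0.5) - sin(0)) + pi / 4)^2
  expect_equal(success_probability(p, 0.5), direct, tolerance = 1e-14)

  # 100 random parameter draws against the same direct expression
  set.seed(42)
  for (i in 1:100) {
    g <- runif(1, 0, 20); om <- runif(1, 0.1, 50)
    phi <- runif(1, 0, 2 * pi); dt <- runif(1, 0.01, 2)
    t <- dt * sample(1:50, 1)
    sp <- signal_params(g, om, phi, dt, 100000L)
    expected <- sin((g / (2 * om)) *
                      (sin(om * t + phi) - sin(om * (t - dt) + phi)) +
                      pi / 4)^2
    expect_equal(success_probability(sp, t), expected, tolerance = 1e-12)
  }
})

test_that("probabilities stay in valid ranges", {
  set.seed(7)
  p <- fig_params()
  vals <- success_probability(p, (1:1000) * 0.5)
  expect_true(all(vals >= 0 & vals <= 1))

  det <- detection_spec(0.6, 0.2)
  q <- detection_probability(runif(200), det)
  expect_true(all(q >= 0.2 & q <= 0.6))
})

test_that("detection model is the two-efficiency mixture", {
  expect_equal(detection_probability(0.37, detection_spec(1, 0)), 0.37)
  expect_equal(detection_probability(c(0.1, 0.9), detection_spec(0.3, 0.3)),
               c(0.3, 0.3))
  expect_equal(detection_probability(0.5, detection_spec(0.074, 0.0518)),
               0.0629, tolerance = 1e-10)
  expect_error(detection_spec(1.2, 0.1), "0, 1")
  expect_error(detection_spec(0.5, 0.6), "eta_false")
})

test_that("parameter validation rejects unphysical inputs", {
  expect_error(signal_params(-1, 10, 0, 0.5, 10), "non-negative")
  expect_error(signal_params(1, 0, 0, 0.5, 10), "positive")
  expect_error(signal_params(1, 10, 0, 0, 10), "positive")
  expect_error(signal_params(1, 10, 0, 0.5, 0), "at least 1")
  # phase normalized into [0, 2*pi)
  expect_equal(signal_params(1, 10, 7, 0.5, 10)$phi, 7 - 2 * pi)
})

test_that("zero-amplitude traces are fair coins", {
  set.seed(11)
  p <- signal_params(0, 10, 0, 0.5, 10000L)
  tr <- simulate_trace(p)
  expect_equal(mean(tr$bits), 0.5, tolerance = 4 * sqrt(0.25 / 10000))
})

test_that("identical seeds give bit-identical datasets", {
  p1 <- fig_params(200L)
  p2 <- fig_params(200L, omega = 10.05)
  a <- simulate_discrimination_dataset(20, p1, p2, seed = 99)
  b <- simulate_discrimination_dataset(20, p1, p2, seed = 99)
  expect_identical(a$bits, b$bits)
  d <- simulate_discrimination_dataset(20, p1, p2, seed = 100)
  expect_false(identical(a$bits, d$bits))
})

test_that("noise variants perturb the trace as specified", {
  set.seed(5)
  p <- fig_params(500L)
  for (v in c("phase_jump", "magnetic_jump", "amplitude_per_interval",
              "mixed")) {
    tr <- simulate_trace(p, noise_spec(v))
    expect_s3_class(tr, "nmr_trace")
    expect_length(tr$bits, 500L)
  }
  # noise defaults resolve against the signal amplitude
  ns <- nanonmr:::resolve_noise(noise_spec("mixed"), g = 10)
  expect_equal(ns$magnetic_sigma, 2)
  expect_equal(ns$amplitude_mean, 10)
  expect_equal(ns$amplitude_sigma, 10)
})

test_that("detection-limited traces have mean (eta_true + eta_false)/2", {
  # the random phase averages P to 1/2, so <x> = (eta_t + eta_f)/2
  set.seed(21)
  le <- low_eff_setup(n_meas = 5000L)
  m <- nanonmr:::simulate_bit_matrix(40, le$p1, noise_spec("none"), le$det,
                                     random_phase = TRUE)
  expected <- (0.074 + 0.0518) / 2
  se <- sqrt(expected * (1 - expected) / length(m))
  expect_equal(mean(m), expected, tolerance = 5 * se / expected)
})

test_that("raw streams segment into non-overlapping windows", {
  set.seed(3)
  bits <- rbinom(100, 1, 0.4)
  ds <- segment_raw_stream(bits, window = 25, dt = 1e-5)
  expect_equal(n_traces(ds), 4L)
  expect_equal(as.vector(t(ds$bits)), bits)

  ds2 <- segment_raw_stream(bits, window = 30, dt = 1e-5)
  expect_equal(n_traces(ds2), 3L)
  expect_equal(ds2$metadata$discarded_bits, 10L)

  # 25000-bit windows at dt = 10 us span 0.25 s
  tr <- get_trace(segment_raw_stream(rep(0:1, 25000), 25000, 1e-5), 1)
  expect_equal(max(trace_times(tr)), 0.25)

  expect_error(segment_raw_stream(bits, window = 200, dt = 1), "shorter")
  # accepts a contiguous character stream
  ds3 <- segment_raw_stream("11001100", window = 4, dt = 1)
  expect_equal(ds3$bits[1, ], c(1L, 1L, 0L, 0L))
})
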