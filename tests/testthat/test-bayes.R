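test_that("log-likelihood matches a term-by-term oracle", {
  # flat model: n * log(0.5)
  p0 <- signal_params(0, 10, 0, 0.5, 64L)
  tr <- nmr_trace(rbinom(64, 1, 0.5), 0.5)
  expect_equal(log_likelihood(tr, p0), 64 * log(0.5), tolerance = 1e-12)

  # 100 random short traces against the brute-force sum, with and without
  # a detection model
  set.seed(26)
  det <- detection_spec(0.3, 0.1)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    g <- runif(1, 0, 15); om <- runif(1, 0.5, 30)
    phi <- runif(1, 0, 2 * pi); dt <- runif(1, 0.05, 1)
    bits <- rbinom(n, 1, 0.5)
    sp <- signal_params(g, om, phi, dt, n)
    tr <- nmr_trace(bits, dt)
    expect_equal(log_likelihood(tr, sp),
                 oracle_loglik(bits, g, om, phi, dt), tolerance = 1e-12)
    d_use <- if (i %% 2 == 0) det else NULL
    expect_equal(log_likelihood(tr, sp, d_use),
                 oracle_loglik(bits, g, om, phi, dt, d_use),
                 tolerance = 1e-12)
  }
})

test_that("log-likelihood is non-positive and finite on extreme probabilities", {
  set.seed(27)
  # strong signal drives P to ~0/1; clipping keeps logs finite
  sp <- signal_params(100, 10, 0.7, 0.5, 50L)
  tr <- nmr_trace(rbinom(50, 1, 0.5), 0.5)
  ll <- log_likelihood(tr, sp)
  expect_true(is.finite(ll))
  expect_lte(ll, 0)
})

test_that("phase maximization improves on finer grids and recovers the phase", {
  set.seed(28)
  p <- fig_params(400L, phi = pi)
  tr <- simulate_trace(p, random_phase = FALSE)

  # grid of one phase reduces to the plain likelihood at phi = 0
  r1 <- max_likelihood_over_phase(tr, p, grid_size = 1, refine = FALSE)
  expect_equal(r1$log_likelihood,
               log_likelihood(tr, signal_params(10, 10, 0, 0.5, 400L)))

  coarse <- max_likelihood_over_phase(tr, p, grid_size = 16, refine = FALSE)
  fine <- max_likelihood_over_phase(tr, p, grid_size = 32, refine = FALSE)
  expect_gte(fine$log_likelihood, coarse$log_likelihood)

  # refinement can only improve on the grid maximum
  ref <- max_likelihood_over_phase(tr, p, grid_size = 16, refine = TRUE)
  expect_gte(ref$log_likelihood, coarse$log_likelihood)

  # ground-truth phase recovered within one grid step
  r <- max_likelihood_over_phase(tr, p, grid_size = 64)
  step <- 2 * pi / 64
  dphi <- abs(r$phi_star - pi)
  expect_lt(min(dphi, 2 * pi - dphi), step)
})

test_that("likelihood-ratio decision breaks ties toward hypothesis 2", {
  # identical hypotheses give exactly equal likelihoods -> label 2
  p <- fig_params(50L)
  tr <- simulate_trace(p, random_phase = FALSE)
  lab <- classify_frequency(tr, p, p, grid_size = 8, refine = FALSE)
  expect_equal(as.integer(lab), 2L)
  expect_equal(attr(lab, "logL1"), attr(lab, "logL2"))
})

test_that("batched dataset classifier agrees with the per-trace path", {
  set.seed(29)
  p1 <- fig_params(300L)
  p2 <- fig_params(300L, omega = 10.08)
  ds <- simulate_discrimination_dataset(15, p1, p2, seed = 30)
  batch <- classify_frequency_dataset(ds, p1, p2, grid_size = 32)
  for (i in c(1, 7, 20)) {
    single <- classify_frequency(get_trace(ds, i), p1, p2, grid_size = 32,
                                 refine = FALSE)
    expect_equal(batch$pred[i], as.integer(single))
    expect_equal(batch$logL1[i], attr(single, "logL1"), tolerance = 1e-9)
  }
})

test_that("likelihood ratio reaches low error at large separation", {
  set.seed(31)
  p1 <- fig_params(1000L)
  p2 <- fig_params(1000L, omega = 10.1)
  ds <- simulate_discrimination_dataset(50, p1, p2, seed = 32)
  res <- classify_frequency_dataset(ds, p1, p2, grid_size = 64)
  expect_lt(error_probability(ds$labels, res$pred)$p_error, 0.05)
})

test_that("indistinguishable hypotheses give chance-level balanced error", {
  set.seed(33)
  p0a <- signal_params(0, 10, 0, 0.5, 400L)
  p0b <- signal_params(0, 10.05, 0, 0.5, 400L)
  ds <- simulate_discrimination_dataset(100, p0a, p0b, seed = 34)
  res <- classify_frequency_dataset(ds, p0a, p0b, grid_size = 16)
  se <- sqrt(0.25 / 100)  # binomial SE per class at p = 0.5
  expect_lt(abs(error_probability(ds$labels, res$pred)$p_error - 0.5),
            3 * se)
})

test_that("OU-bank likelihood maximization behaves as a max over samples", {
  set.seed(35)
  ou <- resolution_ou_params(64)
  model <- resolution_model(10, 0.2, ou, dt = 1, t_total = 64)
  tr <- simulate_resolution_trace(model)

  # a bank holding one all-zero OU sample scores exactly n * log(0.5)
  bank0 <- ou_sample_bank(model, K = 1, seed = 36)
  bank0$samples[[1]]$A[] <- 0
  bank0$samples[[1]]$B[] <- 0
  r0 <- ou_max_likelihood(tr, model, bank0)
  expect_equal(r0$log_likelihood, 64 * log(0.5), tolerance = 1e-10)

  # K = 1 bank: equals the direct Bernoulli sum along those paths
  bank1 <- ou_sample_bank(model, K = 1, seed = 37)
  st <- bank1$samples[[1]]
  t <- (1:64) * 1
  p <- nanonmr:::clip_prob(resolution_probability(model, st$A, st$B, t))
  direct <- sum(tr$bits * log(p) + (1 - tr$bits) * log1p(-p))
  expect_equal(ou_max_likelihood(tr, model, bank1)$log_likelihood, direct,
               tolerance = 1e-10)

  # enlarging the bank never decreases the maximum
  set.seed(38)
  small <- ou_sample_bank(model, K = 5, seed = 39)
  big <- small
  big$samples <- c(small$samples, ou_sample_bank(model, K = 10, seed = 40)$samples)
  expect_gte(ou_max_likelihood(tr, model, big)$log_likelihood,
             ou_max_likelihood(tr, model, small)$log_likelihood)
})

test_that("resolution decision breaks ties toward the double hypothesis", {
  ou <- resolution_ou_params(64)
  model <- resolution_model(10, 0.2, ou, dt = 1, t_total = 32)
  tr <- nmr_trace(rbinom(32, 1, 0.5), 1)
  # a single all-zero OU sample makes both hypotheses score n*log(0.5)
  bank <- ou_sample_bank(model, K = 1, seed = 41)
  bank$samples[[1]]$A[] <- 0
  bank$samples[[1]]$B[] <- 0
  lab <- classify_resolution(tr, 0.2, model, bank)
  expect_equal(as.character(lab), "double")
  expect_equal(attr(lab, "logL1"), attr(lab, "logL2"))
})

test_that("batched resolution classifier matches the per-trace rule", {
  set.seed(42)
  ou <- resolution_ou_params(64)
  model <- resolution_model(10, 0.5, ou, dt = 1, t_total = 64)
  ds <- simulate_resolution_dataset(10, model, seed = 43)
  bank <- ou_sample_bank(model, K = 50, seed = 44)
  batch <- classify_resolution_dataset(ds, 0.5, model, bank)
  for (i in c(1, 11)) {
    single <- classify_resolution(get_trace(ds, i), 0.5, model, bank)
    expect_equal(batch$pred[i], if (single == "single") 1L else 2L)
  }
})
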