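test_that("correlation vectors match hand-computed values", {
  expect_equal(as.numeric(correlation_vector(c(1, 1, 1, 1), k_max = 2)),
               c(1, 1))
  expect_equal(as.numeric(correlation_vector(c(1, 0, 1, 0, 1, 0), k_max = 2)),
               c(-1, 1))
})

test_that("correlation vector equals the brute-force double loop exactly", {
  set.seed(14)
  for (n in c(10, 50, 200)) {
    bits <- rbinom(n, 1, runif(1, 0.2, 0.8))
    k_max <- n - 1L
    got <- correlation_vector(nmr_trace(bits, 1), k_max)
    expect_identical(as.numeric(got), oracle_corr(bits, k_max))
  }
  # lag subsampling picks every stride-th lag
  bits <- rbinom(60, 1, 0.5)
  sub <- correlation_vector(bits, k_max = 50, lag_stride = 5)
  expect_equal(attr(sub, "lags"), seq(1L, 50L, by = 5L))
  expect_identical(as.numeric(sub), oracle_corr(bits, 50)[seq(1, 50, 5)])
})

test_that("correlation vector rejects out-of-range lags", {
  expect_error(correlation_vector(c(1, 0, 1), k_max = 3), "k_max")
  expect_error(correlation_vector(c(1, 0, 1), k_max = 0), "k_max")
})

test_that("templates are class means of correlation vectors", {
  # two identical traces per class: template equals the per-trace vector
  bits <- rbind(c(1, 0, 1, 0, 1, 0), c(1, 0, 1, 0, 1, 0),
                c(1, 1, 1, 1, 1, 1), c(1, 1, 1, 1, 1, 1))
  ds <- nmr_dataset(bits, dt = 1, labels = c(1, 1, 2, 2))
  tm <- fit_templates(ds, k_max = 2)
  expect_equal(tm$templates[[1]], c(-1, 1))
  expect_equal(tm$templates[[2]], c(1, 1))

  # arithmetic mean of distinct vectors
  b2 <- rbind(c(1, 1, 0, 0), c(1, 0, 0, 1), c(0, 0, 0, 0), c(0, 0, 0, 0))
  ds2 <- nmr_dataset(b2, dt = 1, labels = c(1, 1, 2, 2))
  tm2 <- fit_templates(ds2, k_max = 2)
  expect_equal(tm2$templates[[1]],
               (oracle_corr(b2[1, ], 2) + oracle_corr(b2[2, ], 2)) / 2)

  expect_error(fit_templates(nmr_dataset(bits, 1, labels = rep(1, 4))),
               "two classes")
})

test_that("templates on fair-coin data shrink toward zero", {
  set.seed(15)
  p0 <- signal_params(0, 10, 0, 0.5, 200L)
  ds <- simulate_discrimination_dataset(100, p0, p0, seed = 16)
  tm <- fit_templates(ds, k_max = 50)
  # each template lag averages ~100 * 150 independent +-1 products
  expect_lt(max(abs(tm$templates[[1]])), 5 / sqrt(100 * 150))
})

test_that("nearest-template decision follows the L2 rule with ties to class 2", {
  tm <- structure(list(templates = list(c(-1, 1), c(1, 1)),
                       labels = c(1L, 2L), counts = c(2L, 2L),
                       k_max = 2L, lag_stride = 1L),
                  class = "class_templates")
  # trace whose vector equals template 1 exactly
  r <- classify_corr(nmr_trace(c(1, 0, 1, 0, 1, 0), 1), tm)
  expect_equal(as.integer(r), 1L)
  # identical templates: both distances equal, the tie goes to class 2
  tm$templates[[1]] <- tm$templates[[2]]
  r2 <- classify_corr(nmr_trace(c(1, 0, 1, 0, 1, 0), 1), tm)
  expect_equal(as.integer(r2), 2L)
  expect_equal(attr(r2, "D1"), attr(r2, "D2"))
})

test_that("classifier is invariant to training-set order", {
  set.seed(17)
  p1 <- fig_params(300L)
  p2 <- fig_params(300L, omega = 10.05)
  ds <- simulate_discrimination_dataset(30, p1, p2, seed = 18)
  perm <- sample(n_traces(ds))
  ds_perm <- nmr_dataset(ds$bits[perm, ], ds$dt, ds$labels[perm])
  test <- simulate_discrimination_dataset(20, p1, p2, seed = 19)
  r1 <- classify_corr_dataset(test, fit_templates(ds, k_max = 100))
  r2 <- classify_corr_dataset(test, fit_templates(ds_perm, k_max = 100))
  expect_identical(r1$pred, r2$pred)
})

test_that("correlation classifier discriminates strong well-separated signals", {
  set.seed(20)
  p1 <- fig_params(1000L)
  p2 <- fig_params(1000L, omega = 10.1)
  train <- simulate_discrimination_dataset(80, p1, p2, seed = 21)
  test <- simulate_discrimination_dataset(60, p1, p2, seed = 22)
  tm <- fit_templates(train)
  rep <- error_probability(test$labels, classify_corr_dataset(test, tm)$pred)
  expect_lt(rep$p_error, 0.15)
})
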