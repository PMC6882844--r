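test_that("network has the reference architecture and parameter count", {
  net <- build_net(net_spec(1000L), seed = 1)
  n_par <- sum(vapply(net$W, length, 1)) + sum(vapply(net$b, length, 1))
  expect_equal(n_par, 1000 * 20 + 20 + 20 * 35 + 35 + 35 * 1 + 1)  # 20791
  expect_equal(dim(net$W[[1]]), c(1000L, 20L))
  expect_equal(dim(net$W[[2]]), c(20L, 35L))
  expect_equal(dim(net$W[[3]]), c(35L, 1L))
})

test_that("initialization is deterministic given the seed", {
  a <- build_net(net_spec(50L), seed = 7)
  b <- build_net(net_spec(50L), seed = 7)
  expect_identical(a$W, b$W)
  c <- build_net(net_spec(50L), seed = 8)
  expect_false(identical(a$W, c$W))
})

test_that("forward pass matches a hand-coded matrix-multiply oracle", {
  set.seed(44)
  net <- build_net(net_spec(4L, hidden = c(3L, 2L)), seed = 2)
  X <- matrix(rnorm(20), 5, 4)
  ours <- nanonmr:::mlp_forward(net, X)
  oracle <- apply(X, 1L, function(x) {
    h1 <- pmax(as.vector(x %*% net$W[[1]]) + net$b[[1]], 0)
    h2 <- pmax(as.vector(h1 %*% net$W[[2]]) + net$b[[2]], 0)
    z <- sum(h2 * net$W[[3]]) + net$b[[3]]
    1 / (1 + exp(-z))
  })
  expect_equal(ours, oracle, tolerance = 1e-6)
  expect_true(all(ours > 0 & ours < 1))  # Sigmoid range
})

test_that("prediction thresholds strictly at 0.5", {
  net <- build_net(net_spec(3L, hidden = integer(0)), seed = 1)
  net$W[[1]][] <- 0; net$b[[1]][] <- 0
  net$label_map <- c(0L, 1L)
  # zeroed network scores exactly sigmoid(0) = 0.5 -> first label
  r <- predict(net, matrix(c(1, 0, 1), 1))
  expect_equal(r$score, 0.5)
  expect_equal(r$pred, 0L)
  # increasing the output bias strictly increases the score
  net$b[[1]][] <- 0.3
  r2 <- predict(net, matrix(c(1, 0, 1), 1))
  expect_gt(r2$score, 0.5)
  expect_equal(r2$pred, 1L)
})

test_that("training is reproducible and learns a separable toy problem", {
  set.seed(45)
  # two classes with strongly different covariance structure
  n <- 120; d <- 30
  x1 <- matrix(rbinom(n * d, 1, 0.8), n, d)
  x2 <- matrix(rbinom(n * d, 1, 0.2), n, d)
  train <- list(x = rbind(x1, x2), y = rep(c(1L, 2L), each = n))
  cfg <- train_config(max_epochs = 50, batch_size = 32, seed = 3)
  net1 <- train_net(build_net(net_spec(d), seed = 3), train, cfg)
  net2 <- train_net(build_net(net_spec(d), seed = 3), train, cfg)
  expect_identical(net1$W, net2$W)
  expect_identical(net1$history, net2$history)

  set.seed(46)
  xt <- rbind(matrix(rbinom(40 * d, 1, 0.8), 40, d),
              matrix(rbinom(40 * d, 1, 0.2), 40, d))
  pred <- predict(net1, xt)$pred
  truth <- rep(c(1L, 2L), each = 40)
  expect_lt(error_probability(truth, pred)$p_error, 0.05)
  # history records both losses per epoch
  expect_true(all(c("train_mse", "val_mse") %in% names(net1$history)))
})

test_that("training on identical classes stays at chance", {
  set.seed(47)
  x <- matrix(rbinom(200 * 25, 1, 0.5), 200, 25)
  train <- list(x = x, y = rep(c(1L, 2L), each = 100))
  net <- train_net(build_net(net_spec(25L), seed = 4),
                   train, train_config(max_epochs = 30, seed = 4))
  xt <- matrix(rbinom(400 * 25, 1, 0.5), 400, 25)
  pred <- predict(net, xt)$pred
  truth <- rep(c(1L, 2L), each = 200)
  se <- sqrt(0.25 / 200)
  expect_lt(abs(error_probability(truth, pred)$p_error - 0.5), 3 * se + 0.05)
})

test_that("spectral initialization recovers planted carrier frequencies", {
  set.seed(48)
  # two classes of noisy sinusoid-modulated bits at nearby frequencies
  n <- 2000L
  mk <- function(nu, m) {
    t(replicate(m, {
      phi <- runif(1, 0, 2 * pi)
      as.integer(runif(n) < 0.5 + 0.3 * cos(2 * pi * nu * (1:n) + phi))
    }))
  }
  nu1 <- 0.0400; nu2 <- 0.0413
  ds <- nmr_dataset(rbind(mk(nu1, 60), mk(nu2, 60)), dt = 1,
                    labels = rep(1:2, each = 60))
  net <- spectral_init(build_net(net_spec(n), seed = 1), ds)
  got <- sort(net$spectral_freqs[1:2])
  expect_equal(got[1], nu1, tolerance = 0.02)
  expect_equal(got[2], nu2, tolerance = 0.02)
  # signed quadrature quadruples: ReLU pairs realize |z| exactly
  W1 <- net$W[[1]]
  expect_equal(W1[, 1], -W1[, 2])
  expect_equal(W1[, 3], -W1[, 4])
  expect_equal(unname(colSums(W1^2)), rep(1, 20), tolerance = 1e-9)
})

test_that("multi-net training steps replicates through one stream", {
  set.seed(49)
  n <- 120; d <- 30
  train <- list(x = rbind(matrix(rbinom(n * d, 1, 0.8), n, d),
                          matrix(rbinom(n * d, 1, 0.2), n, d)),
                y = rep(1:2, each = n))
  cfg <- train_config(max_epochs = 15, batch_size = 32, seed = 6)
  multi <- train_net_multi(list(build_net(net_spec(d), seed = 21),
                                build_net(net_spec(d), seed = 22)),
                           train, cfg)
  expect_length(multi, 2L)
  # replicates differ (different init) but both learn the easy problem
  expect_false(identical(multi[[1]]$W, multi[[2]]$W))
  xt <- matrix(rbinom(40 * d, 1, 0.8), 40, d)
  for (m in multi) expect_gt(mean(predict(m, xt)$pred == 1), 0.9)
})

test_that("streaming training draws a fresh block each epoch", {
  set.seed(50)
  d <- 20
  val <- list(x = matrix(rbinom(60 * d, 1, 0.5), 60, d),
              y = rep(1:2, each = 30))
  seen <- integer(0)
  gen <- function(ep) {
    seen <<- c(seen, ep)
    list(x = rbind(matrix(rbinom(40 * d, 1, 0.8), 40, d),
                   matrix(rbinom(40 * d, 1, 0.2), 40, d)),
         y = rep(1:2, each = 40))
  }
  net <- train_net(build_net(net_spec(d), seed = 7), val,
                   train_config(max_epochs = 8, patience = 8, seed = 7),
                   fresh_data = gen)
  expect_equal(seen, 1:8)
  expect_equal(nrow(net$history), 8L)
})

test_that("degenerate single-class training is rejected", {
  x <- matrix(rbinom(50 * 10, 1, 0.5), 50, 10)
  expect_error(train_net(build_net(net_spec(10L), seed = 1),
                         list(x = x, y = rep(1L, 50)), train_config()),
               "two classes")
})
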