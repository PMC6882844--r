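#' Feed-forward network architecture
#'
#' The reference classifier is a fully connected feed-forward network of
#' four layers: the input layer (one unit per measurement), two hidden
#' layers of 20 and 35 rectified-linear units, and a single Sigmoid output
#' unit trained with the mean-squared-error loss against 0/1 class labels.
#' A fully connected net is the right shape here because the class
#' information lives in correlations between arbitrarily distant input
#' bits. `hidden = integer(0)` gives a single linear layer into the Sigmoid
#' -- the linear baseline that provably cannot solve the random-phase
#' discrimination problem.
#'
#' @param input_dim trace length fed to the network.
#' @param hidden integer vector of hidden-layer sizes (default `c(20, 35)`).
#' @return an object of class `"net_spec"`.
#' @export
net_spec <- function(input_dim, hidden = c(20L, 35L)) {
  input_dim <- as.integer(input_dim)
  if (input_dim < 1L) stop("'input_dim' must be at least 1")
  hidden <- as.integer(hidden)
  if (any(hidden < 1L)) stop("hidden layer sizes must be positive")
  structure(list(input_dim = input_dim, hidden = hidden,
                 hidden_activation = "relu", output_activation = "sigmoid",
                 loss = "mse"),
            class = "net_spec")
}

#' Training hyper-parameters
#'
#' The reference work specifies the architecture and loss but no training
#' procedure; these are the package's own defaults (Adam with standard
#' moments, mini-batches, early stopping on a held-out validation split).
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size mini-batch size (default 64).
#' @param max_epochs maximum passes over the training data (default 500).
#' @param val_fraction fraction of the training set held out for early
#'   stopping, in `(0, 0.5]` (default 0.2).
#' @param patience epochs without validation improvement before stopping
#'   (default 20).
#' @param seed integer seed controlling shuffling and the validation split
#'   (weight initialization is seeded in [build_net()]).
#' @param encoding `"binary"` feeds bits as 0/1 floats (default);
#'   `"pm1"` as -1/+1.
#' @param center subtract the global training-bit mean from every input
#'   (default `TRUE`); with sparse low-efficiency traces this removes the
#'   large common offset and substantially speeds up learning.
#' @param first_layer_lr_scale multiplier on the learning rate of the
#'   first (input-to-hidden) layer, default 1. Values below 1 protect a
#'   structured initialization (see [spectral_init()]) from being eroded
#'   by gradient noise while the upper layers learn the readout; 0
#'   freezes the first layer.
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-3, batch_size = 64L,
                         max_epochs = 500L, val_fraction = 0.2,
                         patience = 20L, seed = 1L,
                         encoding = c("binary", "pm1"), center = TRUE,
                         first_layer_lr_scale = 1) {
  encoding <- match.arg(encoding)
  if (val_fraction <= 0 || val_fraction > 0.5)
    stop("'val_fraction' must lie in (0, 0.5]")
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            patience >= 1, first_layer_lr_scale >= 0)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 val_fraction = val_fraction,
                 patience = as.integer(patience),
                 seed = as.integer(seed), encoding = encoding,
                 center = center,
                 first_layer_lr_scale = first_layer_lr_scale),
            class = "train_config")
}

#' Initialize a network
#'
#' He-normal weight initialization (`sd = sqrt(2 / fan_in)`), zero biases;
#' deterministic given `seed`.
#'
#' @param spec a [net_spec()].
#' @param seed integer seed for the weight draw.
#' @return an object of class `"mlp_net"`: list with `W` (list of weight
#'   matrices, input-to-output order), `b` (bias vectors), `spec`, and
#'   (after training) `history`, `label_map`, `center`.
#' @export
#' @examples
#' net <- build_net(net_spec(1000), seed = 1)
#' sum(vapply(net$W, length, 1)) + sum(vapply(net$b, length, 1))  # 20791
build_net <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "net_spec"))
  set.seed(seed)
  sizes <- c(spec$input_dim, spec$hidden, 1L)
  W <- vector("list", length(sizes) - 1L)
  b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], 0,
                                  sqrt(2 / sizes[l])),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  structure(list(W = W, b = b, spec = spec, history = NULL,
                 label_map = NULL, center = 0),
            class = "mlp_net")
}

#' @export
print.mlp_net <- function(x, ...) {
  sizes <- c(x$spec$input_dim, x$spec$hidden, 1L)
  n_par <- sum(vapply(x$W, length, 1)) + sum(vapply(x$b, length, 1))
  cat(sprintf("<mlp_net> layers %s (ReLU hidden, Sigmoid output), %d parameters%s\n",
              paste(sizes, collapse = "-"), n_par,
              if (is.null(x$history)) ", untrained" else sprintf(
                ", trained %d epochs", nrow(x$history))))
  invisible(x)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Spectral initialization of the first layer
#'
#' Replaces the first-layer weights with unit-norm sinusoid filters at the
#' dominant frequencies of the training traces' averaged periodogram.
#' Under a random uniform phase the trace covariance is Toeplitz, so its
#' leading eigenvectors are sinusoids at the dominant spectral band;
#' initializing the filters there hands the network the second-order
#' features that gradient descent cannot recover from desk-scale fixed
#' training sets (the covariance spike sits at the detection threshold --
#' see the methods vignette).
#'
#' The peak of each averaged periodogram is located to sub-bin precision
#' by log-parabolic interpolation. When per-trace labels are available the
#' periodogram is averaged per class and each class contributes its own
#' peak frequency (the frequencies enter only through the data; no model
#' parameter is used); without labels a single pooled peak is used.
#' Filters are laid out as signed quadrature quadruples
#' (`cos, -cos, sin, -sin`) at `n_units/4` frequencies -- the peak
#' frequencies plus neighbours offset by `spacing` -- so that a ReLU pair
#' realizes the exact modulus of each quadrature response and the upper
#' layers see band envelopes from the first epoch. Biases and upper
#' layers keep their seeded random initialization; training proceeds as
#' usual.
#'
#' @param net an untrained [build_net()] network whose first hidden layer
#'   has a multiple of 4 units (20 in the reference architecture).
#' @param data an [nmr_dataset()] (labels used if present) or 0/1 matrix.
#' @param labels optional per-trace labels overriding `data$labels`.
#' @param spacing frequency offset between neighbouring filters, in DFT
#'   bins (default 0.5, i.e. half the Fourier resolution of the window).
#' @param max_traces periodogram averaging cap per class (default 400,
#'   evenly subsampled).
#' @return the network with its first layer re-initialized; the filter
#'   frequencies (cycles per sample) are stored as `net$spectral_freqs`.
#' @export
spectral_init <- function(net, data, labels = NULL, spacing = 0.5,
                          max_traces = 400L) {
  stopifnot(inherits(net, "mlp_net"))
  if (length(net$spec$hidden) == 0L)
    stop("spectral initialization needs at least one hidden layer")
  X <- if (inherits(data, "nmr_dataset")) data$bits else data
  if (is.null(labels) && inherits(data, "nmr_dataset")) labels <- data$labels
  n <- ncol(X)
  if (n != net$spec$input_dim)
    stop("trace length does not match the network input dimension")
  mu <- mean(X)

  peak_freq <- function(rows) {
    rows <- rows[unique(round(seq(1L, length(rows),
                                  length.out = min(max_traces,
                                                   length(rows)))))]
    pgram <- 0
    for (i in rows) pgram <- pgram + Mod(stats::fft(X[i, ] - mu))^2
    half <- pgram[2:(n %/% 2)]  # positive frequencies, DC excluded
    k <- which.max(half)
    delta <- 0
    if (k > 1L && k < length(half)) {
      la <- log(half[k - 1]); lb <- log(half[k]); lc <- log(half[k + 1])
      denom <- la - 2 * lb + lc
      if (is.finite(denom) && denom < 0) delta <- 0.5 * (la - lc) / denom
    }
    (k + delta) / n  # cycles per sample
  }

  peaks <- if (is.null(labels)) peak_freq(seq_len(nrow(X))) else
    vapply(sort(unique(labels)), function(l) peak_freq(which(labels == l)),
           numeric(1))

  n_units <- ncol(net$W[[1]])
  if (n_units %% 4L != 0L)
    stop("spectral initialization needs a first layer with a multiple of 4 units")
  n_freqs <- n_units %/% 4L
  dnu <- spacing / n
  freqs <- peaks
  offset <- 1L
  while (length(freqs) < n_freqs) {
    cand <- unique(c(freqs, peaks + offset * dnu, peaks - offset * dnu,
                     mean(peaks)))
    freqs <- cand[seq_len(min(n_freqs, length(cand)))]
    offset <- offset + 1L
  }
  freqs <- freqs[seq_len(n_freqs)]

  t_rel <- seq_len(n)
  W1 <- matrix(0, n, 0)
  for (nu in freqs) {
    cc <- cos(2 * pi * nu * t_rel)
    ss <- sin(2 * pi * nu * t_rel)
    W1 <- cbind(W1, cc, -cc, ss, -ss)
  }
  W1 <- sweep(W1, 2, sqrt(colSums(W1^2)), "/")
  dimnames(W1) <- NULL
  net$W[[1]] <- W1
  net$spectral_freqs <- freqs
  net
}

# Forward pass on a row-matrix of inputs; returns the list of layer
# activations (inputs first, sigmoid output last).
mlp_activations <- function(net, X) {
  A <- list(X)
  nL <- length(net$W)
  for (l in seq_len(nL)) {
    Z <- A[[l]] %*% net$W[[l]]
    Z <- Z + rep(net$b[[l]], each = nrow(Z))
    A[[l + 1L]] <- if (l < nL) pmax(Z, 0) else sigmoid(Z)
  }
  A
}

# Forward pass returning the vector of output scores in (0, 1).
mlp_forward <- function(net, X) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  as.vector(mlp_activations(net, X)[[length(net$W) + 1L]])
}

encode_inputs <- function(bits, encoding, center) {
  X <- bits
  storage.mode(X) <- "double"
  if (encoding == "pm1") X <- 2 * X - 1
  X - center
}

#' Train a network on a labelled dataset
#'
#' Mini-batch Adam on the mean-squared error between the Sigmoid output and
#' 0/1 labels. A `val_fraction` split (class-stratified) is held out; the
#' weights with the best validation loss are kept and training stops after
#' `patience` epochs without improvement. With the seed fixed, training is
#' reproducible.
#'
#' When a `fresh_data` generator is supplied, training runs in streaming
#' mode: every epoch draws a fresh block of labelled traces from the
#' generator and the whole `train` argument serves as the fixed validation
#' set. Streaming makes memorization impossible and raises the effective
#' sample size to (epochs x block size) -- the regime needed for the
#' low-efficiency configuration, where the class signal is second-order
#' and sits at the covariance detection threshold for desk-scale fixed
#' training sets (see the methods vignette). The generator draws from the
#' ambient RNG stream, so the whole run stays reproducible under
#' `cfg$seed`.
#'
#' @param net an untrained [build_net()] network.
#' @param train a labelled [nmr_dataset()] with exactly two classes, or a
#'   list `list(x = matrix, y = labels)`.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses (default `FALSE`).
#' @param fresh_data optional generator `function(epoch)` returning a
#'   labelled [nmr_dataset()] or `list(x, y)` used as that epoch's
#'   training block (streaming mode).
#' @return the trained `"mlp_net"`, with `history` (per-epoch train and
#'   validation MSE), `label_map` (original labels in 0/1 order) and the
#'   input `center` baked in.
#' @export
train_net <- function(net, train, cfg = train_config(), verbose = FALSE,
                      fresh_data = NULL) {
  train_net_multi(list(net), train, cfg, verbose, fresh_data)[[1L]]
}

#' Train several networks on one (possibly streaming) data source
#'
#' Identical to [train_net()] but steps a list of networks (typically the
#' same architecture under different initialization seeds) through the
#' same epochs and mini-batches, so in streaming mode one simulated block
#' feeds every replicate -- this is what makes multi-seed training
#' affordable when data generation dominates the cost. Each network keeps
#' its own optimizer state, best-validation weights and early-stopping
#' counter; training stops when every network has stalled for
#' `cfg$patience` epochs (or at `cfg$max_epochs`).
#'
#' @inheritParams train_net
#' @param nets list of untrained [build_net()] networks.
#' @return list of trained networks, in input order.
#' @export
train_net_multi <- function(nets, train, cfg = train_config(),
                            verbose = FALSE, fresh_data = NULL) {
  stopifnot(is.list(nets), length(nets) >= 1L,
            all(vapply(nets, inherits, TRUE, "mlp_net")),
            inherits(cfg, "train_config"))
  if (inherits(train, "nmr_dataset")) {
    if (is.null(train$labels)) stop("training set must be labelled")
    Xraw <- train$bits; y_lab <- train$labels
  } else {
    Xraw <- train$x; y_lab <- train$y
  }
  labs <- sort(unique(y_lab))
  if (length(labs) != 2L)
    stop("training set must contain exactly two classes")
  for (net in nets)
    if (ncol(Xraw) != net$spec$input_dim)
      stop("trace length does not match the network input dimension")
  y <- as.numeric(match(y_lab, labs) - 1L)

  center <- if (cfg$center) {
    mean(if (cfg$encoding == "pm1") 2 * mean(Xraw) - 1 else mean(Xraw))
  } else 0
  X <- encode_inputs(Xraw, cfg$encoding, center)

  set.seed(cfg$seed)
  if (is.null(fresh_data)) {
    # class-stratified validation split
    val_idx <- unlist(lapply(0:1, function(cl) {
      rows <- which(y == cl)
      sample(rows, max(1L, round(cfg$val_fraction * length(rows))))
    }))
    tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
    Xv <- X[val_idx, , drop = FALSE]; yv <- y[val_idx]
    Xt <- X[tr_idx, , drop = FALSE]; yt <- y[tr_idx]
  } else {
    # streaming mode: the supplied set is the fixed validation set
    Xv <- X; yv <- y
    Xt <- NULL; yt <- NULL
  }
  take_block <- function(ep) {
    blk <- fresh_data(ep)
    if (inherits(blk, "nmr_dataset")) blk <- list(x = blk$bits,
                                                  y = blk$labels)
    list(x = encode_inputs(blk$x, cfg$encoding, center),
         y = as.numeric(match(blk$y, labs) - 1L))
  }

  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  nn <- length(nets)
  st <- lapply(nets, function(net) {
    list(W = net$W, b = net$b,
         mW = lapply(net$W, function(w) w * 0),
         vW = lapply(net$W, function(w) w * 0),
         mb = lapply(net$b, function(x) x * 0),
         vb = lapply(net$b, function(x) x * 0),
         it = 0L, stall = 0L,
         best = list(W = net$W, b = net$b, loss = Inf, epoch = 0L),
         hist_tr = numeric(0), hist_val = numeric(0))
  })

  fwd <- function(s, X) {
    A <- X
    nL <- length(s$W)
    for (l in seq_len(nL)) {
      Z <- A %*% s$W[[l]]
      Z <- Z + rep(s$b[[l]], each = nrow(Z))
      A <- if (l < nL) pmax(Z, 0) else sigmoid(Z)
    }
    as.vector(A)
  }

  for (ep in seq_len(cfg$max_epochs)) {
    if (!is.null(fresh_data)) {
      blk <- take_block(ep)
      Xt <- blk$x; yt <- blk$y
    }
    idx <- sample(length(yt))
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    for (k in seq_len(nn)) {
      if (st[[k]]$stall >= cfg$patience) next
      s <- st[[k]]
      nL <- length(s$W)
      for (bt in batches) {
        s$it <- s$it + 1L
        A <- list(Xt[bt, , drop = FALSE])
        for (l in seq_len(nL)) {
          Z <- A[[l]] %*% s$W[[l]]
          Z <- Z + rep(s$b[[l]], each = nrow(Z))
          A[[l + 1L]] <- if (l < nL) pmax(Z, 0) else sigmoid(Z)
        }
        out <- as.vector(A[[nL + 1L]])
        delta <- matrix(2 * (out - yt[bt]) / length(bt) * out * (1 - out),
                        ncol = 1L)
        for (l in nL:1) {
          lr_l <- cfg$learning_rate *
            if (l == 1L) (cfg$first_layer_lr_scale %||% 1) else 1
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L) delta <- tcrossprod(delta, s$W[[l]]) * (A[[l]] > 0)
          if (lr_l == 0) next
          s$mW[[l]] <- beta1 * s$mW[[l]] + (1 - beta1) * gW
          s$vW[[l]] <- beta2 * s$vW[[l]] + (1 - beta2) * gW^2
          s$mb[[l]] <- beta1 * s$mb[[l]] + (1 - beta1) * gb
          s$vb[[l]] <- beta2 * s$vb[[l]] + (1 - beta2) * gb^2
          s$W[[l]] <- s$W[[l]] -
            lr_l * (s$mW[[l]] / (1 - beta1^s$it)) /
            (sqrt(s$vW[[l]] / (1 - beta2^s$it)) + adam_eps)
          s$b[[l]] <- s$b[[l]] -
            lr_l * (s$mb[[l]] / (1 - beta1^s$it)) /
            (sqrt(s$vb[[l]] / (1 - beta2^s$it)) + adam_eps)
        }
      }
      loss_tr <- mean((fwd(s, Xt) - yt)^2)
      loss_val <- mean((fwd(s, Xv) - yv)^2)
      s$hist_tr <- c(s$hist_tr, loss_tr)
      s$hist_val <- c(s$hist_val, loss_val)
      if (verbose)
        message(sprintf("epoch %3d net %d  train MSE %.5f  val MSE %.5f",
                        ep, k, loss_tr, loss_val))
      if (loss_val < s$best$loss - 1e-9) {
        s$best <- list(W = s$W, b = s$b, loss = loss_val, epoch = ep)
        s$stall <- 0L
      } else {
        s$stall <- s$stall + 1L
      }
      st[[k]] <- s
    }
    if (all(vapply(st, function(s) s$stall >= cfg$patience, TRUE))) break
  }

  for (k in seq_len(nn)) {
    s <- st[[k]]
    nets[[k]]$W <- s$best$W
    nets[[k]]$b <- s$best$b
    nets[[k]]$history <- data.frame(epoch = seq_along(s$hist_tr),
                                    train_mse = s$hist_tr,
                                    val_mse = s$hist_val)
    nets[[k]]$best_epoch <- s$best$epoch
    nets[[k]]$label_map <- labs
    nets[[k]]$center <- center
    nets[[k]]$encoding <- cfg$encoding
  }
  nets
}

#' Score and classify traces with a trained network
#'
#' The score is the Sigmoid output in `(0, 1)`; the label is the second
#' class if the score is strictly greater than 0.5, else the first (a score
#' of exactly 0.5 maps to the first class: the decision rule's ">0.5" is
#' strict).
#'
#' @param object a trained [train_net()] network.
#' @param newdata an [nmr_trace()], an [nmr_dataset()], or a 0/1 matrix
#'   with one trace per row.
#' @param ... unused.
#' @return a data.frame with one row per trace: `score` and `pred` (in the
#'   original label space when the net was trained on labelled data).
#' @export
predict.mlp_net <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "nmr_dataset")) newdata$bits
       else if (inherits(newdata, "nmr_trace")) matrix(newdata$bits, 1L)
       else if (is.matrix(newdata)) newdata
       else matrix(newdata, nrow = 1L)
  if (ncol(X) != object$spec$input_dim)
    stop("trace length does not match the network input dimension")
  X <- encode_inputs(X, object$encoding %||% "binary", object$center)
  score <- mlp_forward(object, X)
  cls <- as.integer(score > 0.5)
  pred <- if (is.null(object$label_map)) cls else object$label_map[cls + 1L]
  data.frame(score = score, pred = pred)
}
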