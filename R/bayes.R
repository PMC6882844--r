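# Probabilities are clipped away from {0, 1} before taking logs so that
# measure-zero outcomes keep the log-likelihood finite.
LIK_EPS <- 1e-12

clip_prob <- function(p, eps = LIK_EPS) pmin(pmax(p, eps), 1 - eps)

# Bernoulli log-likelihood of bit matrix X (traces x n) under each column
# of the probability matrix Q (n x K): returns the N x K matrix
#   L[i, k] = sum_j x_ij log Q_jk + (1 - x_ij) log(1 - Q_jk).
# Written as one matrix product on the log-odds plus a constant row.
batch_log_likelihood <- function(X, Q) {
  Q <- clip_prob(Q)
  const <- colSums(log1p(-Q))
  X %*% (log(Q) - log1p(-Q)) + rep(const, each = nrow(X))
}

#' Bernoulli log-likelihood of a trace under one signal hypothesis
#'
#' `sum_j [ x_j log P(t_j) + (1 - x_j) log(1 - P(t_j)) ]`, with `P` the
#' single-frequency success probability at the hypothesis parameters
#' (including its phase `params$phi`), passed through the detection model
#' when `det` is given. Probabilities are clipped to `[1e-12, 1 - 1e-12]`
#' before the logs, so the result is finite for any trace; it is always
#' `<= 0`.
#'
#' @param trace an [nmr_trace()].
#' @param params a [signal_params()]; `params$dt` must equal the trace's.
#' @param det a [detection_spec()] or `NULL`.
#' @return scalar log-likelihood (natural log).
#' @export
log_likelihood <- function(trace, params, det = NULL) {
  stopifnot(inherits(trace, "nmr_trace"), inherits(params, "signal_params"))
  if (!isTRUE(all.equal(trace$dt, params$dt)))
    stop("trace and hypothesis disagree on 'dt'")
  if (length(trace$bits) != params$n_meas)
    stop("trace length does not match 'n_meas' of the hypothesis")
  p <- success_probability(params, trace_times(trace))
  if (!is.null(det)) p <- detection_probability(p, det)
  p <- clip_prob(p)
  sum(trace$bits * log(p) + (1 - trace$bits) * log1p(-p))
}

# Success-probability matrix over a phase grid: n_meas x length(phis).
phase_probability_matrix <- function(params, phis, det = NULL) {
  t <- seq_len(params$n_meas) * params$dt
  Q <- vapply(phis, function(phi)
    p_ramsey(params$g, params$omega, phi, params$dt, t),
    numeric(params$n_meas))
  if (!is.null(det)) Q <- detection_probability(Q, det)
  Q
}

#' Maximal log-likelihood over the unknown phase
#'
#' The phase of the signal is a nuisance parameter, uniform on `[0, 2*pi)`.
#' The likelihood is evaluated on a uniform grid of `grid_size` phases and,
#' optionally, refined by a local continuous maximization (golden-section /
#' parabolic search via [stats::optimize()]) within one grid step of the
#' grid argmax -- the likelihood is smooth and 2*pi-periodic in the phase,
#' so the refinement is a strict improvement.
#'
#' @param trace an [nmr_trace()].
#' @param params a [signal_params()] carrying the hypothesis amplitude and
#'   frequency; its `phi` field is ignored.
#' @param grid_size number of uniform grid phases (>= 1; default 128).
#' @param det a [detection_spec()] or `NULL`.
#' @param refine apply the local continuous refinement (default `TRUE`).
#' @return an object of class `"likelihood_result"`: a list with
#'   `log_likelihood` and `phi_star` (the maximizing phase).
#' @export
max_likelihood_over_phase <- function(trace, params, grid_size = 128,
                                      det = NULL, refine = TRUE) {
  stopifnot(inherits(trace, "nmr_trace"), inherits(params, "signal_params"))
  grid_size <- as.integer(grid_size)
  if (grid_size < 1L) stop("'grid_size' must be at least 1")
  phis <- seq(0, 2 * pi, length.out = grid_size + 1L)[seq_len(grid_size)]
  Q <- phase_probability_matrix(params, phis, det)
  L <- drop(batch_log_likelihood(matrix(trace$bits, 1L), Q))
  k <- which.max(L)
  best <- list(log_likelihood = L[k], phi_star = phis[k])
  if (refine && grid_size >= 2L) {
    step <- 2 * pi / grid_size
    f <- function(phi) {
      p <- clip_prob(drop(phase_probability_matrix(
        signal_params(params$g, params$omega, phi, params$dt, params$n_meas),
        phi, det)))
      sum(trace$bits * log(p) + (1 - trace$bits) * log1p(-p))
    }
    opt <- stats::optimize(f, interval = c(phis[k] - step, phis[k] + step),
                           maximum = TRUE, tol = step * 1e-3)
    if (opt$objective > best$log_likelihood)
      best <- list(log_likelihood = opt$objective,
                   phi_star = opt$maximum %% (2 * pi))
  }
  structure(best, class = "likelihood_result")
}

#' @export
print.likelihood_result <- function(x, ...) {
  cat(sprintf("<likelihood_result> logL = %.6g, argmax = %s\n",
              x$log_likelihood, format(x$phi_star %||% x$k_star)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full-Bayesian frequency discrimination of one trace
#'
#' Likelihood-ratio test between two known-frequency hypotheses: the
#' phase-maximized log-likelihood is computed under each and the hypothesis
#' with the larger value is returned. Ties go to the second hypothesis (the
#' "otherwise" branch of the decision rule).
#'
#' @param trace an [nmr_trace()].
#' @param params1,params2 [signal_params()] of the two hypotheses.
#' @param grid_size phase-grid size (default 128).
#' @param det a [detection_spec()], a list of two (one per hypothesis), or
#'   `NULL`.
#' @param refine refine the phase maximum continuously (default `TRUE`).
#' @return integer label `1L` or `2L`, with attributes `logL1`, `logL2`.
#' @export
classify_frequency <- function(trace, params1, params2, grid_size = 128,
                               det = NULL, refine = TRUE) {
  dets <- if (is.null(det) || inherits(det, "detection_spec"))
    list(det, det) else det
  L1 <- max_likelihood_over_phase(trace, params1, grid_size, dets[[1]],
                                  refine)$log_likelihood
  L2 <- max_likelihood_over_phase(trace, params2, grid_size, dets[[2]],
                                  refine)$log_likelihood
  structure(if (L1 > L2) 1L else 2L, logL1 = L1, logL2 = L2)
}

#' Full-Bayesian discrimination of a whole dataset
#'
#' Batched version of [classify_frequency()]: the phase-grid probability
#' matrices are built once per hypothesis and all traces are scored with
#' two matrix products, which is what makes the likelihood-ratio test on
#' thousands of long traces affordable.
#'
#' @inheritParams classify_frequency
#' @param ds an [nmr_dataset()].
#' @param grid_size phase-grid size (default 64).
#' @param refine refine each trace's phase maximum continuously around the
#'   grid argmax (default `FALSE`; the grid alone is accurate for the grid
#'   sizes used here).
#' @return a data.frame with one row per trace: `pred` (1/2), `logL1`,
#'   `logL2`, and `score = logL1 - logL2` (useful for ROC curves).
#' @export
classify_frequency_dataset <- function(ds, params1, params2, grid_size = 64,
                                       det = NULL, refine = FALSE) {
  stopifnot(inherits(ds, "nmr_dataset"))
  dets <- if (is.null(det) || inherits(det, "detection_spec"))
    list(det, det) else det
  phis <- seq(0, 2 * pi, length.out = grid_size + 1L)[seq_len(grid_size)]
  X <- ds$bits
  storage.mode(X) <- "double"
  maxL <- function(params, d) {
    Q <- phase_probability_matrix(params, phis, d)
    L <- batch_log_likelihood(X, Q)
    list(L = apply(L, 1L, max), k = max.col(L))
  }
  r1 <- maxL(params1, dets[[1]])
  r2 <- maxL(params2, dets[[2]])
  L1 <- r1$L; L2 <- r2$L
  if (refine) {
    step <- 2 * pi / grid_size
    for (i in seq_len(nrow(X))) {
      tr <- get_trace(ds, i)
      L1[i] <- max_likelihood_over_phase(tr, params1, grid_size, dets[[1]],
                                         refine = TRUE)$log_likelihood
      L2[i] <- max_likelihood_over_phase(tr, params2, grid_size, dets[[2]],
                                         refine = TRUE)$log_likelihood
    }
  }
  data.frame(pred = ifelse(L1 > L2, 1L, 2L), logL1 = L1, logL2 = L2,
             score = L1 - L2)
}
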