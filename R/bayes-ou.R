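#' Pre-drawn bank of OU realizations
#'
#' The resolution likelihood has no closed form in the OU nuisance paths, so
#' the maximum is taken over a Monte-Carlo bank of `K` pre-drawn stationary
#' realization sets, each holding one path per quadrature amplitude on the
#' measurement grid. The same bank object can be evaluated under any
#' hypothesis sharing the grid and component count (the raw OU draws do not
#' depend on the component frequencies), which guarantees that the two
#' hypotheses' likelihoods differ only through the model and not through
#' the Monte-Carlo draw.
#'
#' @param model a [resolution_model()] supplying the grid, component count
#'   and OU parameters.
#' @param K number of realization sets (default 1000).
#' @param seed optional integer for reproducibility.
#' @param scheme OU discretization scheme, see [ou_path()].
#' @return an object of class `"ou_sample_bank"`.
#' @export
ou_sample_bank <- function(model, K = 1000, seed = NULL, scheme = "exact") {
  stopifnot(inherits(model, "resolution_model"))
  K <- as.integer(K)
  if (K < 1L) stop("'K' must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  samples <- vector("list", K)
  for (k in seq_len(K)) samples[[k]] <- draw_ou_states(model, scheme)
  structure(list(samples = samples, n_meas = model$n_meas, dt = model$dt,
                 n_components = model$n_components, ou = model$ou,
                 seed = seed),
            class = "ou_sample_bank")
}

#' @export
print.ou_sample_bank <- function(x, ...) {
  cat(sprintf("<ou_sample_bank> K = %d realization sets, %d x %d grid\n",
              length(x$samples), x$n_components, x$n_meas))
  invisible(x)
}

# Success-probability matrix (n_meas x K) of every bank sample under a
# given hypothesis model.
bank_probability_matrix <- function(bank, model) {
  if (bank$n_meas != model$n_meas || !isTRUE(all.equal(bank$dt, model$dt)))
    stop("bank grid does not match the model grid")
  if (bank$n_components != model$n_components)
    stop("bank and model disagree on the number of components")
  t <- seq_len(model$n_meas) * model$dt
  vapply(bank$samples, function(s)
    resolution_probability(model, s$A, s$B, t),
    numeric(model$n_meas))
}

#' Maximal log-likelihood over sampled OU realizations
#'
#' For each realization set `O_k` in the bank, the Bernoulli log-likelihood
#' of the trace under the hypothesis model evaluated along `O_k` is
#' computed; the maximum over `k` is returned. Enlarging the bank can only
#' increase the result.
#'
#' @param trace an [nmr_trace()].
#' @param model a [resolution_model()] (the hypothesis).
#' @param bank an [ou_sample_bank()] on the same measurement grid.
#' @return a `"likelihood_result"`: `log_likelihood` and `k_star` (index of
#'   the maximizing realization set).
#' @export
ou_max_likelihood <- function(trace, model, bank) {
  stopifnot(inherits(trace, "nmr_trace"), inherits(bank, "ou_sample_bank"))
  if (length(trace$bits) != model$n_meas)
    stop("trace length does not match the model grid")
  P <- bank_probability_matrix(bank, model)
  L <- drop(batch_log_likelihood(matrix(trace$bits, 1L), P))
  k <- which.max(L)
  structure(list(log_likelihood = L[k], k_star = k),
            class = "likelihood_result")
}

#' Full-Bayesian single- vs double-frequency resolution of one trace
#'
#' Likelihood-ratio test between the single-frequency hypothesis
#' (`delta_sep = 0`) and the double-frequency hypothesis
#' (`delta_sep = delta_n`), each maximized over its OU realization bank.
#' Ties go to `"double"` (the "otherwise" branch of the decision rule).
#'
#' @param trace an [nmr_trace()].
#' @param delta_n double-hypothesis frequency separation, rad/s (> 0).
#' @param model a [resolution_model()] supplying `delta_c`, OU parameters
#'   and the grid (its own `delta_sep` is ignored).
#' @param bank0 an [ou_sample_bank()] for the single-frequency hypothesis.
#' @param bank1 bank for the double-frequency hypothesis; defaults to
#'   `bank0` (shared draws, so the likelihoods differ only through the
#'   model).
#' @return `"single"` or `"double"`, with attributes `logL1`, `logL2`.
#' @export
classify_resolution <- function(trace, delta_n, model, bank0,
                                bank1 = bank0) {
  if (delta_n <= 0) stop("'delta_n' must be positive")
  m0 <- resolution_model(model$delta_c, 0, model$ou, model$dt,
                         model$t_total, model$n_components)
  m1 <- resolution_model(model$delta_c, delta_n, model$ou, model$dt,
                         model$t_total, model$n_components)
  L1 <- ou_max_likelihood(trace, m0, bank0)$log_likelihood
  L2 <- ou_max_likelihood(trace, m1, bank1)$log_likelihood
  structure(if (L1 > L2) "single" else "double", logL1 = L1, logL2 = L2)
}

#' Full-Bayesian resolution of a whole dataset
#'
#' Batched version of [classify_resolution()]: the two bank probability
#' matrices are built once and all traces are scored by matrix products.
#'
#' @inheritParams classify_resolution
#' @param ds an [nmr_dataset()] on the model's grid.
#' @return a data.frame with one row per trace: `pred` (`1` = single,
#'   `2` = double), `logL1`, `logL2`, `score = logL1 - logL2`.
#' @export
classify_resolution_dataset <- function(ds, delta_n, model, bank0,
                                        bank1 = bank0) {
  stopifnot(inherits(ds, "nmr_dataset"))
  if (delta_n <= 0) stop("'delta_n' must be positive")
  m0 <- resolution_model(model$delta_c, 0, model$ou, model$dt,
                         model$t_total, model$n_components)
  m1 <- resolution_model(model$delta_c, delta_n, model$ou, model$dt,
                         model$t_total, model$n_components)
  X <- ds$bits
  storage.mode(X) <- "double"
  L1 <- apply(batch_log_likelihood(X, bank_probability_matrix(bank0, m0)),
              1L, max)
  L2 <- apply(batch_log_likelihood(X, bank_probability_matrix(bank1, m1)),
              1L, max)
  data.frame(pred = ifelse(L1 > L2, 1L, 2L), logL1 = L1, logL2 = L2,
             score = L1 - L2)
}
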