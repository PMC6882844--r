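#' Ornstein-Uhlenbeck process parameters
#'
#' Models the slowly fluctuating quadrature amplitudes of a statistically
#' polarized nano-NMR signal. In SDE form
#' `dx = -theta * (x - mu) dt + sigma dW`, so `theta = 1/tau` is the
#' reversion speed (inverse relaxation time) and `sigma^2` the diffusion
#' constant; the stationary law is `Normal(mu, sigma^2 / (2 theta))`.
#'
#' @param mu stationary mean, rad/s (amplitude units).
#' @param theta reversion speed, 1/s; must be > 0.
#' @param sigma volatility, rad s^-3/2; must be >= 0.
#' @return an object of class `"ou_params"`.
#' @seealso [ou_path()], [resolution_ou_params()]
#' @export
ou_params <- function(mu = 0, theta, sigma) {
  stopifnot(is.numeric(mu), is.numeric(theta), is.numeric(sigma))
  if (theta <= 0) stop("'theta' must be positive")
  if (sigma < 0) stop("'sigma' must be non-negative")
  structure(list(mu = mu, theta = theta, sigma = sigma), class = "ou_params")
}

#' @export
print.ou_params <- function(x, ...) {
  cat(sprintf(
    "<ou_params> mu = %g, theta = %g 1/s (tau = %g s), sigma = %g; stationary sd = %g\n",
    x$mu, x$theta, 1 / x$theta, x$sigma, x$sigma / sqrt(2 * x$theta)))
  invisible(x)
}

#' Standard OU parameters of the resolution study
#'
#' For a signal of coherence time `T2`, the quadrature amplitudes follow a
#' zero-mean OU process with volatility `sigma = (pi/10) * sqrt(4/(pi*T2))`
#' and reversion speed `theta = 1/T2`, giving a stationary amplitude
#' standard deviation `sigma / sqrt(2/T2) = (pi/10) * sqrt(2/pi)`
#' independent of `T2`.
#'
#' @param T2 signal coherence time, s.
#' @return an [ou_params()].
#' @export
resolution_ou_params <- function(T2 = 256) {
  ou_params(mu = 0, theta = 1 / T2, sigma = (pi / 10) * sqrt(4 / (pi * T2)))
}

#' Sample a discretized OU path
#'
#' Returns the process at the `n_steps` grid times `0, dt, ..., (n-1)*dt`
#' (relative to the path start). The default scheme is the exact AR(1)
#' transition `x' = mu + (x - mu) e^(-theta dt) + s z` with
#' `s^2 = sigma^2 (1 - e^(-2 theta dt)) / (2 theta)`, whose marginals are
#' exact at any step size; `"euler"` applies the literal Euler-Maruyama
#' update `x' = x - theta (x - mu) dt + sigma sqrt(dt) z` instead. Unless
#' `x0` is given, the initial state is drawn from the stationary
#' distribution, so the whole path is stationary.
#'
#' @param ou an [ou_params()].
#' @param n_steps number of grid points (>= 1).
#' @param dt grid spacing, s.
#' @param x0 optional fixed initial state.
#' @param scheme `"exact"` (default) or `"euler"`.
#' @return numeric vector of length `n_steps`.
#' @export
#' @examples
#' set.seed(1)
#' x <- ou_path(resolution_ou_params(256), n_steps = 512, dt = 1)
ou_path <- function(ou, n_steps, dt, x0 = NULL,
                    scheme = c("exact", "euler")) {
  stopifnot(inherits(ou, "ou_params"))
  scheme <- match.arg(scheme)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L) stop("'n_steps' must be at least 1")
  if (dt <= 0) stop("'dt' must be positive")
  sd_stat <- ou$sigma / sqrt(2 * ou$theta)
  x <- numeric(n_steps)
  x[1] <- if (is.null(x0)) stats::rnorm(1, ou$mu, sd_stat) else x0
  if (n_steps == 1L) return(x)
  if (scheme == "exact") {
    a <- exp(-ou$theta * dt)
    s <- sd_stat * sqrt(1 - a^2)
    z <- stats::rnorm(n_steps - 1L)
    for (k in 2:n_steps) x[k] <- ou$mu + (x[k - 1] - ou$mu) * a + s * z[k - 1]
  } else {
    z <- stats::rnorm(n_steps - 1L)
    for (k in 2:n_steps)
      x[k] <- x[k - 1] - ou$theta * (x[k - 1] - ou$mu) * dt +
        ou$sigma * sqrt(dt) * z[k - 1]
  }
  x
}

#' Multi-component OU-modulated signal model (frequency resolution)
#'
#' The resolution problem asks whether a trace was generated by one central
#' frequency `delta_c` or by two frequencies `delta_c +/- delta_sep/2`. Each
#' component `i` carries two quadrature amplitudes `A_i(t)`, `B_i(t)`, all
#' following independent copies of the same OU process, so the signal has
#' strong amplitude and phase noise. `delta_sep = 0` encodes the
#' single-frequency hypothesis (the components collapse onto `delta_c`).
#'
#' @param delta_c central frequency, rad/s (> 0).
#' @param delta_sep frequency separation, rad/s (>= 0).
#' @param ou an [ou_params()] shared by all quadrature amplitudes.
#' @param dt interrogation interval, s.
#' @param t_total total measurement time, s; the trace length is
#'   `floor(t_total / dt)`.
#' @param n_components number of frequency components (default 2).
#' @return an object of class `"resolution_model"`.
#' @export
#' @examples
#' resolution_model(delta_c = 10, delta_sep = 0.05,
#'                  ou = resolution_ou_params(256), dt = 1, t_total = 512)
resolution_model <- function(delta_c, delta_sep, ou, dt, t_total,
                             n_components = 2L) {
  stopifnot(inherits(ou, "ou_params"))
  if (delta_c <= 0) stop("'delta_c' must be positive")
  if (delta_sep < 0) stop("'delta_sep' must be non-negative")
  if (dt <= 0 || t_total < dt) stop("need 0 < dt <= t_total")
  n_components <- as.integer(n_components)
  if (!n_components %in% c(1L, 2L))
    stop("'n_components' must be 1 or 2")
  deltas <- if (n_components == 1L) delta_c else
    delta_c + c(-0.5, 0.5) * delta_sep
  if (any(deltas <= 0))
    stop("component frequencies delta_c +/- delta_sep/2 must be positive")
  structure(
    list(delta_c = delta_c, delta_sep = delta_sep, deltas = deltas,
         ou = ou, dt = dt, t_total = t_total,
         n_meas = as.integer(floor(t_total / dt)),
         n_components = n_components),
    class = "resolution_model"
  )
}

#' @export
print.resolution_model <- function(x, ...) {
  cat(sprintf(
    "<resolution_model> %d component(s) at %s rad/s (delta_c = %g, sep = %g)\n",
    x$n_components, paste(format(x$deltas), collapse = ", "),
    x$delta_c, x$delta_sep))
  cat(sprintf("  dt = %g s, T_tot = %g s (%d measurements); OU tau = %g s\n",
              x$dt, x$t_total, x$n_meas, 1 / x$ou$theta))
  invisible(x)
}

#' Success probability of the OU-modulated multi-component signal
#'
#' For quadrature amplitudes held at their values at the measurement time,
#' the bright-state probability is
#' `sin^2( sum_i (A_i/delta_i)(sin(delta_i t) - sin(delta_i (t - dt)))
#'       + (B_i/delta_i)(cos(delta_i t) - cos(delta_i (t - dt))) + pi/4 )`.
#'
#' `A` and `B` may be vectors of length `n_components` (one time point) or
#' matrices of shape `n_components x length(t)`.
#'
#' @param model a [resolution_model()].
#' @param A,B quadrature amplitude values at the measurement time(s), rad/s.
#' @param t measurement time(s), s; each >= `model$dt`.
#' @return probability vector in `[0, 1]`.
#' @export
resolution_probability <- function(model, A, B, t) {
  stopifnot(inherits(model, "resolution_model"))
  if (any(t < model$dt)) stop("'t' must be at least one interval dt")
  nc <- model$n_components
  A <- if (is.matrix(A)) A else matrix(A, nrow = nc, ncol = length(t))
  B <- if (is.matrix(B)) B else matrix(B, nrow = nc, ncol = length(t))
  if (nrow(A) != nc || nrow(B) != nc)
    stop("'A' and 'B' must supply one value per component")
  bracket <- 0
  for (i in seq_len(nc)) {
    d <- model$deltas[i]
    bracket <- bracket +
      (A[i, ] / d) * (sin(d * t) - sin(d * (t - model$dt))) +
      (B[i, ] / d) * (cos(d * t) - cos(d * (t - model$dt)))
  }
  sin(bracket + pi / 4)^2
}

# Draw one full set of OU quadrature paths on the model's measurement grid:
# a list of matrices A, B of shape n_components x n_meas.
draw_ou_states <- function(model, scheme = "exact") {
  n <- model$n_meas
  A <- matrix(0, model$n_components, n)
  B <- matrix(0, model$n_components, n)
  for (i in seq_len(model$n_components)) {
    A[i, ] <- ou_path(model$ou, n, model$dt, scheme = scheme)
    B[i, ] <- ou_path(model$ou, n, model$dt, scheme = scheme)
  }
  list(A = A, B = B)
}

#' Simulate a trace from the OU-modulated resolution model
#'
#' Samples independent stationary OU paths for every quadrature amplitude on
#' the measurement grid, evaluates the multi-component success probability
#' at each measurement time (amplitudes held constant within an interval),
#' and draws the bits.
#'
#' @param model a [resolution_model()].
#' @param label optional label stored on the trace.
#' @param scheme OU discretization scheme, see [ou_path()].
#' @return an [nmr_trace()].
#' @export
simulate_resolution_trace <- function(model, label = NULL, scheme = "exact") {
  stopifnot(inherits(model, "resolution_model"))
  st <- draw_ou_states(model, scheme)
  t <- seq_len(model$n_meas) * model$dt
  p <- resolution_probability(model, st$A, st$B, t)
  nmr_trace(as.integer(stats::runif(model$n_meas) < p), model$dt,
            label = label)
}

#' Simulate a labelled single- vs double-frequency dataset
#'
#' `n_per_class` traces from the single-frequency model (`delta_sep = 0`,
#' label `1`) and from the double-frequency model (`delta_sep = delta_n`,
#' label `2`), sharing `delta_c`, OU parameters and time grid.
#'
#' @param n_per_class traces per hypothesis.
#' @param model a [resolution_model()] whose `delta_sep` is taken as the
#'   double-frequency separation `delta_n`.
#' @param seed optional integer for reproducibility.
#' @param scheme OU discretization scheme.
#' @return an [nmr_dataset()] with labels `1` (single) / `2` (double).
#' @export
simulate_resolution_dataset <- function(n_per_class, model, seed = NULL,
                                        scheme = "exact") {
  stopifnot(inherits(model, "resolution_model"))
  if (!is.null(seed)) set.seed(seed)
  m0 <- resolution_model(model$delta_c, 0, model$ou, model$dt,
                         model$t_total, model$n_components)
  sim <- function(mod, n) {
    m <- matrix(0L, n, mod$n_meas)
    for (i in seq_len(n)) m[i, ] <- simulate_resolution_trace(mod, scheme = scheme)$bits
    m
  }
  bits <- rbind(sim(m0, n_per_class), sim(model, n_per_class))
  nmr_dataset(bits, model$dt,
              labels = rep(c(1L, 2L), each = n_per_class),
              metadata = list(delta_c = model$delta_c,
                              delta_n = model$delta_sep,
                              ou = unclass(model$ou),
                              t_total = model$t_total, seed = seed,
                              scheme = scheme))
}
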