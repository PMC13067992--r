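# Latent-process simulator: four exemplar stochastic differential equations
# (exponential/Ornstein-Uhlenbeck growth, logistic growth, cusp catastrophe,
# damped oscillator) integrated by Euler-Maruyama, then subsampled onto an
# equidistant observation grid with independent N(0,1) measurement error.

#' Drift functions of the exemplar processes
#'
#' Instantaneous deterministic rate of change of each latent process.
#' `drift_logistic` returns `r*y*(1 - y/k)`; `drift_exponential` is the
#' mean-reverting (Ornstein-Uhlenbeck-type) drift `r*(k - y)`, largest in
#' magnitude at the start and zero at the asymptote; `drift_cusp` is the
#' canonical cusp gradient `a(t) + b*y - y^3` whose slowly cycling normal
#' factor `a(t)` drives sudden switches between the two stable branches; and
#' `drift_oscillator` is the damped linear oscillator `(dy, dv) =
#' (v, -omega^2*y - zeta*v)`.
#'
#' @param y Current process value (for the oscillator, position).
#' @param r Growth-rate constant (1/time), `r > 0`.
#' @param k Asymptote / carrying capacity; `k > 0` for the logistic.
#' @param t Current time (cusp only).
#' @param cusp_a Function of time giving the normal-factor control.
#' @param cusp_b Bifurcation-factor constant.
#' @param v Current velocity (oscillator only).
#' @param omega Angular frequency (1/time), `omega > 0`.
#' @param zeta Damping coefficient (1/time), `zeta >= 0`.
#' @return A scalar rate, except `drift_oscillator` which returns `c(dy, dv)`.
#' @examples
#' drift_logistic(5, r = 1, k = 10) # 2.5
#' drift_oscillator(1, 0, omega = 2, zeta = 0) # c(0, -4)
#' @export
drift_logistic <- function(y, r, k) {
  if (!all(is.finite(c(y, r, k)))) stop("non-finite input to drift_logistic")
  if (k <= 0) stop("logistic carrying capacity `k` must be positive")
  r * y * (1 - y / k)
}

#' @rdname drift_logistic
#' @export
drift_exponential <- function(y, r, k) {
  if (!all(is.finite(c(y, r, k)))) stop("non-finite input to drift_exponential")
  if (r <= 0) stop("growth rate `r` must be positive")
  r * (k - y)
}

#' @rdname drift_logistic
#' @export
drift_cusp <- function(y, t, cusp_a, cusp_b) {
  a <- if (is.function(cusp_a)) cusp_a(t) else cusp_a
  if (!all(is.finite(c(y, t, a, cusp_b)))) stop("non-finite input to drift_cusp")
  a + cusp_b * y - y^3
}

#' @rdname drift_logistic
#' @export
drift_oscillator <- function(y, v, omega, zeta) {
  if (!all(is.finite(c(y, v, omega, zeta)))) {
    stop("non-finite input to drift_oscillator")
  }
  if (omega <= 0) stop("angular frequency `omega` must be positive")
  if (zeta < 0) stop("damping `zeta` must be non-negative")
  c(v, -omega^2 * y - zeta * v)
}

# Default parameters: chosen once so that each process displays its
# characteristic behaviour over the 84-unit full period (growth ~95% of the
# asymptote near mid-period; ~5 decaying oscillation cycles; 2-3 cusp
# switches). See the methods vignette for the reasoning.
default_process_params <- function(name) {
  switch(name,
    exponential = list(r = 0.07, k = 10, y0 = 0),
    # reflect_at = 0: the logistic drift is destabilizing below zero, so the
    # additive Wiener noise would otherwise eject rare paths from the basin
    logistic = list(r = 0.14, k = 10, y0 = 0.5, reflect_at = 0),
    cusp = list(cusp_amp = 3, cusp_period = 56, cusp_b = 3, y0 = -sqrt(3)),
    oscillator = list(omega = 2 * pi / 16.8, zeta = 0.055, y0 = 5, v0 = 0),
    stop("unknown process `", name, "`; valid: exponential, logistic, ",
         "cusp, oscillator")
  )
}

#' Specify a latent stochastic process
#'
#' Creates the drift/diffusion definition of one of the four exemplar latent
#' processes. Unsupplied parameters take package defaults calibrated so each
#' process shows its characteristic behaviour over the default 84-unit period.
#'
#' @param name One of `"exponential"`, `"logistic"`, `"cusp"`, `"oscillator"`.
#' @param sigma Dynamic-error diffusion scale (outcome units per square-root
#'   time unit), `sigma >= 0`. For a dynamic-error variance `v` per unit time
#'   step use `sigma = sqrt(v)`.
#' @param ... Process parameters overriding the defaults: `r`, `k`, `y0` for
#'   the growth curves (the logistic additionally takes `reflect_at`, a
#'   reflecting lower barrier defaulting to 0 that keeps noisy paths inside
#'   the logistic basin, where the drift is stabilising; set it to `NULL` for
#'   an unbounded simulation); `cusp_amp`, `cusp_period`, `cusp_b`, `y0` for
#'   the cusp
#'   (the normal factor cycles as `a(t) = cusp_amp * sin(2*pi*t/cusp_period)`);
#'   `omega`, `zeta`, `y0`, `v0` for the oscillator.
#' @return An object of class `process_spec`.
#' @examples
#' sp <- process_spec("logistic", sigma = 1)
#' traj <- euler_maruyama(sp, dt = 1/300, span = 84, seed = 1)
#' @export
process_spec <- function(name = c("exponential", "logistic", "cusp",
                                  "oscillator"),
                         sigma = 1, ...) {
  name <- match.arg(name)
  if (!is.finite(sigma) || sigma < 0) stop("`sigma` must be >= 0")
  params <- utils::modifyList(default_process_params(name), list(...))
  if (name %in% c("exponential", "logistic") && params$r <= 0) {
    stop("growth rate `r` must be positive")
  }
  if (name == "logistic" && params$k <= 0) stop("`k` must be positive")
  if (name == "oscillator") {
    if (params$omega <= 0) stop("`omega` must be positive")
    if (params$zeta < 0) stop("`zeta` must be non-negative")
  }
  structure(list(name = name, sigma = sigma, params = params),
            class = "process_spec")
}

#' @export
print.process_spec <- function(x, ...) {
  pv <- paste(names(x$params), signif(unlist(x$params), 4), sep = " = ",
              collapse = ", ")
  cat(sprintf("<process_spec: %s> sigma = %g; %s\n", x$name, x$sigma, pv))
  invisible(x)
}

# Drift evaluated on the full state (scalar, or (y, v) for the oscillator).
drift_of <- function(spec) {
  p <- spec$params
  switch(spec$name,
    exponential = function(state, t) drift_exponential(state, p$r, p$k),
    logistic = function(state, t) drift_logistic(state, p$r, p$k),
    cusp = {
      a_fun <- function(t) p$cusp_amp * sin(2 * pi * t / p$cusp_period)
      function(state, t) drift_cusp(state, t, a_fun, p$cusp_b)
    },
    oscillator = function(state, t) {
      drift_oscillator(state[1], state[2], p$omega, p$zeta)
    }
  )
}

#' Simulate a latent trajectory by Euler-Maruyama
#'
#' Integrates the stochastic differential equation `dy = drift(y, t) dt +
#' sigma dW_t` on an equidistant fine grid: `y[i+1] = y[i] + drift * dt +
#' sigma * sqrt(dt) * z[i]` with independent standard-normal `z[i]`. For the
#' damped oscillator the Wiener increment perturbs the velocity equation only.
#'
#' @param spec A [process_spec()].
#' @param dt Fine-grid step (time units); must divide `span` into an integer
#'   number of steps. The default 1/300 divides the observation spacings 1,
#'   1/2 and 1/3 exactly, so subsampling needs no interpolation.
#' @param span Total simulated time.
#' @param seed Integer RNG seed; identical inputs give identical trajectories.
#' @return An object of class `latent_trajectory`: list with `times` (fine
#'   grid), `values` (latent `f(t)`), `dt`, `seed`, and for the oscillator the
#'   velocity path in `velocity`.
#' @export
euler_maruyama <- function(spec, dt = 1 / 300, span = 84, seed = 1) {
  stopifnot(inherits(spec, "process_spec"))
  if (dt <= 0) stop("`dt` must be positive")
  n_steps <- span / dt
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("`span` must be an integer number of `dt` steps")
  }
  n_steps <- as.integer(round(n_steps))
  times <- seq(0, by = dt, length.out = n_steps + 1)
  drift <- drift_of(spec)
  two_dim <- spec$name == "oscillator"

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  z <- stats::rnorm(n_steps)

  sqdt <- sqrt(dt)
  if (two_dim) {
    y <- numeric(n_steps + 1)
    v <- numeric(n_steps + 1)
    y[1] <- spec$params$y0
    v[1] <- spec$params$v0
    for (i in seq_len(n_steps)) {
      d <- drift(c(y[i], v[i]), times[i])
      y[i + 1] <- y[i] + d[1] * dt
      v[i + 1] <- v[i] + d[2] * dt + spec$sigma * sqdt * z[i]
      if (abs(y[i + 1]) > 1e6) {
        stop(sprintf("process `%s` diverged at step %d (t = %g)",
                     spec$name, i, times[i + 1]))
      }
    }
  } else {
    reflect_at <- spec$params$reflect_at   # NULL for unbounded processes
    y <- numeric(n_steps + 1)
    y[1] <- spec$params$y0
    for (i in seq_len(n_steps)) {
      y[i + 1] <- y[i] + drift(y[i], times[i]) * dt + spec$sigma * sqdt * z[i]
      if (!is.null(reflect_at) && y[i + 1] < reflect_at) {
        y[i + 1] <- 2 * reflect_at - y[i + 1]
      }
      if (abs(y[i + 1]) > 1e6) {
        stop(sprintf("process `%s` diverged at step %d (t = %g)",
                     spec$name, i, times[i + 1]))
      }
    }
    v <- NULL
  }
  structure(list(times = times, values = y, velocity = v, dt = dt,
                 seed = as.integer(seed), process = spec$name),
            class = "latent_trajectory")
}

#' @export
print.latent_trajectory <- function(x, ...) {
  cat(sprintf("<latent_trajectory: %s> %d points, dt = %g, span = %g\n",
              x$process, length(x$times), x$dt, max(x$times)))
  invisible(x)
}

#' Define an observation sampling design
#'
#' Equidistant sampling over the first half or the full period: observations
#' at `0, 1/frequency, ..., span`, giving `span * frequency + 1` observations
#' where `span` is `full_span` (full period) or `full_span / 2` (half).
#'
#' @param period `"half"` or `"full"`.
#' @param frequency Observations per unit time step: 1, 2 or 3.
#' @param full_span Total duration of the full period (default 84, so the
#'   design sizes are 43, 85, 127 for the half period and 85, 169, 253 for
#'   the full period).
#' @param noise_sd Measurement-error standard deviation (default 1: standard
#'   normal measurement error).
#' @return An object of class `sampling_design`.
#' @examples
#' d <- sampling_design("half", 1)
#' length(design_grid_times(d)) # 43
#' @export
sampling_design <- function(period = c("full", "half"), frequency = 1,
                            full_span = 84, noise_sd = 1) {
  period <- match.arg(period)
  if (!frequency %in% c(1L, 2L, 3L)) {
    stop("`frequency` must be 1, 2 or 3 observations per time step")
  }
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  span <- if (period == "half") full_span / 2 else full_span
  structure(list(period = period, frequency = as.integer(frequency),
                 full_span = full_span, span = span, noise_sd = noise_sd),
            class = "sampling_design")
}

#' Observation times of a sampling design
#'
#' @param design A [sampling_design()].
#' @return Numeric vector `0, 1/frequency, ..., span` of length
#'   `span * frequency + 1`.
#' @export
design_grid_times <- function(design) {
  stopifnot(inherits(design, "sampling_design"))
  (0:(design$span * design$frequency)) / design$frequency
}

#' Subsample a latent trajectory and add measurement error
#'
#' Picks the latent values on the design's observation grid (which must fall
#' exactly on the fine simulation grid) and adds independent Gaussian
#' measurement error with SD `design$noise_sd`.
#'
#' @param traj A `latent_trajectory` from [euler_maruyama()].
#' @param design A [sampling_design()].
#' @param seed Integer RNG seed for the measurement errors.
#' @return An [observed_series()] with the latent truth attached.
#' @export
sample_observations <- function(traj, design, seed = 1) {
  stopifnot(inherits(traj, "latent_trajectory"),
            inherits(design, "sampling_design"))
  obs_times <- design_grid_times(design)
  if (max(obs_times) > max(traj$times) + 1e-9) {
    stop("trajectory span is shorter than the sampling design span")
  }
  idx <- round(obs_times / traj$dt) + 1
  if (any(abs(traj$times[idx] - obs_times) > 1e-8)) {
    stop("observation grid does not align with the simulation grid; ",
         "use a finer `dt` that divides 1/frequency exactly")
  }
  latent <- traj$values[idx]

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  y <- latent + design$noise_sd * stats::rnorm(length(latent))
  observed_series(obs_times, y, latent = latent)
}

#' Simulate one observed series end to end
#'
#' Convenience wrapper: builds the process and design, integrates the latent
#' path over the design span, subsamples and adds measurement error. The
#' dynamic-error variance per unit time step `dev` is mapped to the diffusion
#' scale as `sigma = sqrt(dev)`.
#'
#' @param process Process name (see [process_spec()]).
#' @param dev Dynamic-error variance per unit time step, e.g. 0.5, 1 or 2.
#' @param period,frequency,full_span,noise_sd See [sampling_design()].
#' @param seed Integer master seed for this series (drives both the latent
#'   path and the measurement errors).
#' @param dt Euler-Maruyama step.
#' @param ... Extra process parameters passed to [process_spec()].
#' @return An [observed_series()] with latent truth and the `dev` condition
#'   recorded.
#' @examples
#' s <- simulate_series("logistic", dev = 1, period = "half", frequency = 1,
#'                      seed = 7)
#' length(s$times) # 43
#' @export
simulate_series <- function(process, dev = 1, period = "full", frequency = 1,
                            full_span = 84, noise_sd = 1, seed = 1,
                            dt = 1 / 300, ...) {
  spec <- process_spec(process, sigma = sqrt(dev), ...)
  design <- sampling_design(period, frequency, full_span, noise_sd)
  traj <- euler_maruyama(spec, dt = dt, span = design$span, seed = seed)
  noise_seed <- as.integer((as.numeric(seed) + 500009) %% 2147483647)
  out <- sample_observations(traj, design, seed = noise_seed)
  out$dynamic_error_variance <- dev
  out
}
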