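# Study orchestration: enumerate the factorial design, simulate, fit every
# method, score, and collect tidy records; plus the idiographic screening
# demo on synthetic multi-person data.

#' Observation times for one design cell
#'
#' Equidistant times `0, 1/frequency, ..., span`, with `span = full_span`
#' (full period) or `full_span / 2` (half period), so the sample size is
#' `span * frequency + 1`.
#'
#' @inheritParams sampling_design
#' @return Numeric vector of observation times.
#' @examples
#' length(design_grid("half", 1)) # 43
#' length(design_grid("full", 3)) # 253
#' @export
design_grid <- function(period = c("full", "half"), frequency = 1,
                        full_span = 84) {
  design_grid_times(sampling_design(period, frequency, full_span))
}

# Deterministic per-replicate substream seed below 2^31.
derive_seed <- function(master_seed, cell_index, replicate) {
  as.integer((as.numeric(master_seed) * 48271 + cell_index * 63689 +
                replicate * 378551) %% 2147483629 + 1)
}

# Fit one method to a series, returning a smoother_fit or a non-converged
# placeholder; individual failures never abort the study.
fit_method <- function(series, method, gp_estimation = "map",
                       gam_k = NULL) {
  if (is.null(gam_k)) gam_k <- min(length(series$times), 35)
  res <- tryCatch(
    switch(method,
      lpr = lpr_fit(series),
      gp = gp_fit(series, estimation = gp_estimation),
      gam = gam_fit(series, K = gam_k),
      poly = poly_fit(series),
      stop("unknown method `", method, "`")
    ),
    error = function(e) NULL
  )
  if (is.null(res)) {
    ne <- length(series$times)
    res <- smoother_fit(method, series$times, rep(NA_real_, ne),
                        rep(NA_real_, ne), rep(NA_real_, ne),
                        rep(NA_real_, ne), hat = NULL,
                        wiggliness = c(value = NA_real_), converged = FALSE)
  }
  res
}

#' Run the factorial simulation study
#'
#' For every design cell (process x dynamic-error variance x sampling period
#' x sampling frequency) and replicate: simulate an observed series, fit each
#' requested method, and score it (MSE and interval coverage against the
#' latent truth, hat-matrix GCV against the observations). Fit failures are
#' recorded as non-converged rows with `NA` scores, never aborting the study.
#' Deterministic given `master_seed`; per-replicate seeds are derived
#' substreams and recorded in the output.
#'
#' @param processes Process names (default all four).
#' @param dev Dynamic-error variances (default `c(0.5, 1, 2)`).
#' @param period Sampling periods (default both `"half"` and `"full"`).
#' @param frequency Sampling frequencies (default `1:3`).
#' @param replicates Replicates per cell (default 100; reduce for desk-scale
#'   runs).
#' @param methods Subset of `c("lpr", "gp", "gam", "poly")`.
#' @param master_seed Integer master seed.
#' @param gp_estimation GP hyperparameter estimation mode (default `"map"`).
#' @param gam_k GAM basis dimension; default `NULL` lets the basis grow with
#'   the data as `min(n_obs, 35)`, large enough for every exemplar process.
#' @param full_span Full-period duration (default 84).
#' @param dt Euler-Maruyama step for the latent simulation.
#' @param verbose Print per-cell progress to stderr.
#' @return Data frame of records: one row per cell x replicate x method with
#'   columns `process`, `dev`, `period`, `frequency`, `replicate`, `seed`,
#'   `method`, `n_obs`, `mse`, `gcv`, `coverage`, `wiggliness`, `converged`.
#' @examples
#' r <- run_study(processes = "logistic", dev = 1, period = "half",
#'                frequency = 1, replicates = 2, methods = c("gam", "poly"),
#'                master_seed = 1)
#' nrow(r) # 4
#' @export
run_study <- function(processes = c("exponential", "logistic", "cusp",
                                    "oscillator"),
                      dev = c(0.5, 1, 2),
                      period = c("half", "full"),
                      frequency = 1:3,
                      replicates = 100,
                      methods = c("lpr", "gp", "gam", "poly"),
                      master_seed = 1,
                      gp_estimation = "map", gam_k = NULL,
                      full_span = 84, dt = 1 / 300,
                      verbose = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  cells <- expand.grid(process = processes, dev = dev, period = period,
                       frequency = frequency, stringsAsFactors = FALSE,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells) * replicates * length(methods))
  ri <- 0L
  for (ci in seq_len(nrow(cells))) {
    cell <- cells[ci, ]
    if (verbose) {
      message(sprintf("cell %d/%d: %s dev=%g %s f=%d", ci, nrow(cells),
                      cell$process, cell$dev, cell$period, cell$frequency))
    }
    for (rep_i in seq_len(replicates)) {
      seed <- derive_seed(master_seed, ci, rep_i)
      series <- simulate_series(cell$process, dev = cell$dev,
                                period = cell$period,
                                frequency = cell$frequency,
                                full_span = full_span, seed = seed, dt = dt)
      for (m in methods) {
        fit <- fit_method(series, m, gp_estimation = gp_estimation,
                          gam_k = gam_k)
        scr <- if (fit$converged) {
          list(
            mse = tryCatch(mse(fit, series), error = function(e) NA_real_),
            gcv = tryCatch(gcv_score(fit, series),
                           error = function(e) NA_real_),
            coverage = tryCatch(ci_coverage(fit, series),
                                error = function(e) NA_real_)
          )
        } else {
          list(mse = NA_real_, gcv = NA_real_, coverage = NA_real_)
        }
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          process = cell$process, dev = cell$dev, period = cell$period,
          frequency = cell$frequency, replicate = rep_i, seed = seed,
          method = m, n_obs = length(series$times),
          mse = scr$mse, gcv = scr$gcv, coverage = scr$coverage,
          wiggliness = unname(fit$wiggliness[1]),
          converged = fit$converged, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(ri)])
  rownames(out) <- NULL
  out
}

#' Simulate one synthetic person's series for the idiographic demo
#'
#' Emulates a week-long momentary-assessment protocol (default 70 equidistant
#' assessments: 7 days of 10) on a 0-100 response scale. `"linear"` persons
#' follow a linear trend plus noise; `"floor"` persons sit near the scale
#' floor (responses truncated at 0); `"wiggly"` persons follow a strong slow
#' sine plus noise.
#'
#' @param kind `"linear"`, `"floor"` or `"wiggly"`.
#' @param n_obs Number of assessments.
#' @param seed Integer seed.
#' @return An [observed_series()] (no latent truth; this mimics real data).
#' @export
simulate_person <- function(kind = c("linear", "floor", "wiggly"),
                            n_obs = 70, seed = 1) {
  kind <- match.arg(kind)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(as.integer(seed))
  t <- seq(0, 7, length.out = n_obs)
  y <- switch(kind,
    linear = {
      a <- stats::runif(1, 20, 60)
      b <- stats::runif(1, -5, 5)
      a + b * t + stats::rnorm(n_obs, 0, 8)
    },
    floor = pmax(0, stats::rnorm(n_obs, 2, 3)),
    wiggly = {
      a <- stats::runif(1, 30, 60)
      amp <- stats::runif(1, 15, 25)
      per <- stats::runif(1, 2, 4)
      ph <- stats::runif(1, 0, 2 * pi)
      a + amp * sin(2 * pi * t / per + ph) + stats::rnorm(n_obs, 0, 8)
    }
  )
  observed_series(t, pmin(pmax(y, 0), 100))
}

#' Idiographic screening demo on synthetic persons
#'
#' Fits a GAM with a single smooth of time to each synthetic person's series
#' and classifies the estimated trend as effectively linear (`EDF <
#' threshold`) or non-linear, mirroring an exploratory screen of momentary
#' assessment data.
#'
#' @param n_persons Number of persons.
#' @param mix Named proportions over `c("linear", "floor", "wiggly")`
#'   (normalised internally).
#' @param seed Integer master seed.
#' @param threshold EDF classification threshold (default 1.001).
#' @param n_obs Assessments per person (default 70).
#' @return List with `table` (data frame: person, kind, edf, linear),
#'   `counts` (linear/nonlinear), and `edf`.
#' @examples
#' demo <- run_idiographic_demo(6, mix = c(linear = 1), seed = 1)
#' demo$counts
#' @export
run_idiographic_demo <- function(n_persons = 117,
                                 mix = c(linear = 0.45, floor = 0.17,
                                         wiggly = 0.38),
                                 seed = 1, threshold = 1.001, n_obs = 70) {
  kinds_avail <- c("linear", "floor", "wiggly")
  mix <- mix[intersect(kinds_avail, names(mix))]
  if (length(mix) == 0 || any(mix < 0) || sum(mix) <= 0) {
    stop("`mix` must give non-negative proportions for at least one kind")
  }
  mix <- mix / sum(mix)
  if (n_persons == 0) {
    return(list(table = data.frame(person = integer(), kind = character(),
                                   edf = numeric(), linear = logical()),
                counts = c(linear = 0L, nonlinear = 0L), edf = numeric()))
  }
  # deterministic composition: largest-remainder apportionment of n_persons
  target <- mix * n_persons
  base <- floor(target)
  left <- n_persons - sum(base)
  if (left > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  kinds <- rep(names(base), times = base)
  edf <- numeric(n_persons)
  for (i in seq_len(n_persons)) {
    s <- simulate_person(kinds[i], n_obs = n_obs,
                         seed = derive_seed(seed, 9999L, i))
    f <- gam_fit(s)
    edf[i] <- unname(f$wiggliness[["edf"]])
  }
  cls <- classify_idiographic(edf, threshold)
  list(table = data.frame(person = seq_len(n_persons), kind = kinds,
                          edf = edf, linear = cls$linear,
                          stringsAsFactors = FALSE),
       counts = cls$counts, edf = edf)
}
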