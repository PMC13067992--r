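# Penalized-spline GAM with a single smooth of time. The smooth is built
# from an intercept, a linear term, and K-2 radial cubic basis functions
# |t - knot|^3 at quantile knots (time internally rescaled to [0, 1]); the
# penalty is the exact bending energy of the radial block over the data
# range, so affine functions are unpenalized. The smoothing weight lambda is
# selected by generalized cross-validation on a log-spaced grid.

#' Build the spline basis and penalty for a single smooth of time
#'
#' Columns of the design matrix: intercept, linear time, and `K - 2`
#' column-centred radial functions `|t - knot|^3` at quantile knots (time
#' rescaled to `[0, 1]`, which makes fits invariant to affine changes of the
#' time axis). The penalty matrix `S` is the curvature (bending-energy) Gram
#' matrix of the radial block, `S[j,k] = 36 * integral(|t - k_j| |t - k_k|)`
#' over the data range, in closed form; it is positive semi-definite with the
#' affine functions `{1, t}` as its exact null space.
#'
#' @param obs_times Observation times (used for knot placement and scaling).
#' @param K Total basis dimension (intercept + linear + `K - 2` radial),
#'   `4 <= K <= length(obs_times)`.
#' @return List with `X` (n x K design), `S` (K x K penalty), `knots` (on the
#'   rescaled axis), `centers` (column means removed from the radial block),
#'   and `t_range`, plus `eval` — a function mapping new times to design rows.
#' @export
build_basis <- function(obs_times, K = 10) {
  n <- length(obs_times)
  if (K < 4) stop("`K` must be at least 4")
  if (K > n) stop("`K` cannot exceed the number of observations")
  t_range <- range(obs_times)
  if (diff(t_range) <= 0) stop("observation times are degenerate")
  ts <- (obs_times - t_range[1]) / diff(t_range)
  knots <- unname(stats::quantile(ts, probs = seq(0, 1, length.out = K - 2)))
  if (anyDuplicated(knots)) {
    stop("duplicate knots from tied observation times; reduce `K`")
  }
  radial <- abs(outer(ts, knots, `-`))^3
  centers <- colMeans(radial)
  X <- cbind(1, ts, sweep(radial, 2, centers))
  S <- matrix(0, K, K)
  S[3:K, 3:K] <- curvature_gram(knots)
  eval_fun <- function(new_times) {
    tn <- (new_times - t_range[1]) / diff(t_range)
    rn <- abs(outer(tn, knots, `-`))^3
    cbind(1, tn, sweep(rn, 2, centers))
  }
  list(X = X, S = S, knots = knots, centers = centers, t_range = t_range,
       eval = eval_fun)
}

# Gram matrix of the second derivatives 6|t - knot_j| over [0, 1]:
# G[j,k] = 36 * int_0^1 |t - a||t - b| dt, closed form per segment.
curvature_gram <- function(knots) {
  m <- length(knots)
  G <- matrix(0, m, m)
  for (j in seq_len(m)) {
    for (k in j:m) {
      a <- min(knots[j], knots[k])
      b <- max(knots[j], knots[k])
      P <- function(t) t^3 / 3 - (a + b) * t^2 / 2 + a * b * t
      val <- 2 * P(a) - 2 * P(b) + P(1)        # P(0) = 0
      G[j, k] <- G[k, j] <- 36 * val
    }
  }
  G
}

#' Penalized spline fit at a fixed smoothing weight
#'
#' Solves `(X'X + lambda S) beta = X'y`; the hat matrix is
#' `X (X'X + lambda S)^{-1} X'`, the smooth's effective degrees of freedom
#' are `trace(H) - 1`, and the 95% credible band uses the coefficient
#' covariance `(X'X + lambda S)^{-1} sigma^2` with
#' `sigma^2 = RSS / (n - trace(H))` (lambda treated as fixed).
#'
#' @param series An [observed_series()] or `data.frame(time, y)`.
#' @param lambda Positive smoothing weight.
#' @param K Basis dimension, see [build_basis()].
#' @param basis Optionally a prebuilt [build_basis()] result.
#' @return List with `coefficients`, `fitted`, `edf`, `hat`, `sigma2`,
#'   `cov_beta`, `rss`, `trace_hat`, and the `basis`.
#' @export
fit_penalized <- function(series, lambda, K = 10, basis = NULL) {
  series <- as_series(series)
  if (lambda <= 0) stop("`lambda` must be positive")
  if (is.null(basis)) basis <- build_basis(series$times, K)
  X <- basis$X
  n <- nrow(X)
  M <- crossprod(X) + lambda * basis$S
  Mi <- tryCatch(solve(M), error = function(e) {
    stop("singular penalized system; increase `lambda` or reduce `K`")
  })
  beta <- drop(Mi %*% crossprod(X, series$y))
  H <- X %*% Mi %*% t(X)
  fitted <- drop(H %*% series$y)
  tr_h <- sum(diag(H))
  rss <- sum((series$y - fitted)^2)
  sigma2 <- if (n - tr_h > 1e-8) rss / (n - tr_h) else 0
  list(coefficients = beta, fitted = fitted, edf = tr_h - 1, hat = H,
       sigma2 = sigma2, cov_beta = Mi * sigma2, rss = rss, trace_hat = tr_h,
       basis = basis, lambda = lambda)
}

#' Select the smoothing weight by generalized cross-validation
#'
#' Minimises `GCV(lambda) = n * RSS(lambda) / (n - trace(H(lambda)))^2` over
#' a log-spaced grid; under (numerical) ties the largest lambda wins,
#' favouring the smoother fit.
#'
#' @inheritParams fit_penalized
#' @param lambda_grid Candidate values (default 60 log-spaced points between
#'   `1e-6` and `1e6`).
#' @return The selected lambda (scalar).
#' @export
select_lambda_gcv <- function(series, K = 10,
                              lambda_grid = 10^seq(-6, 6, length.out = 60),
                              basis = NULL) {
  series <- as_series(series)
  if (is.null(basis)) basis <- build_basis(series$times, K)
  n <- length(series$y)
  scores <- vapply(lambda_grid, function(l) {
    f <- tryCatch(fit_penalized(series, l, basis = basis),
                  error = function(e) NULL)
    if (is.null(f) || n - f$trace_hat <= 0) return(Inf)
    n * f$rss / (n - f$trace_hat)^2
  }, numeric(1))
  if (all(!is.finite(scores))) {
    stop("GCV undefined for every candidate lambda (interpolating fits)")
  }
  best <- min(scores[is.finite(scores)])
  tol <- max(1e-6 * abs(best), 1e-12 * n * stats::var(series$y))
  max(lambda_grid[is.finite(scores) & scores <= best + tol])
}

#' Generalized additive model fit (single smooth of time)
#'
#' Penalized-spline smooth of time with GCV-selected (or fixed) smoothing
#' weight, returning the unified [smoother_fit()]. The wiggliness summary is
#' the smooth's effective degrees of freedom, `trace(H) - 1`, ranging from 1
#' (a linear smooth) to `K - 1`.
#'
#' @inheritParams fit_penalized
#' @param lambda Positive smoothing weight, or `"auto"` (default) for GCV
#'   selection via [select_lambda_gcv()].
#' @param eval_points Prediction times (default: observation times).
#' @return A [smoother_fit()] with `wiggliness = c(edf = ...)` and the
#'   penalized-fit detail in `$extra`.
#' @examples
#' s <- observed_series(0:30, 0.5 * (0:30) + 2)
#' f <- gam_fit(s)
#' unname(round(f$wiggliness, 3)) # ~1: linear smooth
#' @export
gam_fit <- function(series, K = 10, lambda = "auto", eval_points = NULL) {
  series <- as_series(series)
  basis <- build_basis(series$times, K)
  l <- if (identical(lambda, "auto")) {
    select_lambda_gcv(series, K, basis = basis)
  } else {
    stopifnot(is.numeric(lambda), lambda > 0)
    lambda
  }
  pf <- fit_penalized(series, l, basis = basis)
  if (is.null(eval_points)) eval_points <- series$times
  Xe <- basis$eval(eval_points)
  est <- drop(Xe %*% pf$coefficients)
  se <- sqrt(pmax(0, rowSums((Xe %*% pf$cov_beta) * Xe)))
  M <- crossprod(basis$X) + l * basis$S
  He <- Xe %*% solve(M, t(basis$X))
  smoother_fit(
    method = "gam", eval_points = eval_points, estimate = est, se = se,
    lower = est - Z95 * se, upper = est + Z95 * se, hat = He,
    wiggliness = c(edf = pf$edf), converged = TRUE,
    extra = list(lambda = l, K = K, fit = pf)
  )
}
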