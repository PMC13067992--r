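# Local polynomial regression: at each evaluation point t*, a weighted least
# squares polynomial of degree p in (t - t*) is fitted with kernel weights
# k((t - t*)/h); the estimate is the local intercept. The map from y to the
# estimates is linear, so the full hat matrix is available for GCV scoring.

#' Kernel weight functions
#'
#' Weight at absolute scaled distance `u = |t - t*| / h`.
#'
#' @param u Non-negative scaled distance(s).
#' @param kernel `"epanechnikov"` (default; `0.75 * (1 - u^2)` on `u <= 1`),
#'   `"gaussian"` (`exp(-u^2/2)/sqrt(2*pi)`), or `"uniform"` (`0.5` on
#'   `u <= 1`).
#' @return Numeric weights, same length as `u`.
#' @examples
#' kernel_weight(0, "epanechnikov") # 0.75
#' @export
kernel_weight <- function(u, kernel = c("epanechnikov", "gaussian",
                                        "uniform")) {
  if (any(u < 0, na.rm = TRUE)) stop("`u` must be a non-negative distance")
  kernel <- match.arg(kernel)
  switch(kernel,
    epanechnikov = 0.75 * pmax(0, 1 - u^2) * (u <= 1),
    gaussian = exp(-u^2 / 2) / sqrt(2 * pi),
    uniform = 0.5 * (u <= 1)
  )
}

#' Local weighted polynomial fit at a single time point
#'
#' Solves the kernel-weighted normal equations at `t_star`: with design
#' columns `(t - t_star)^0 ... (t - t_star)^p` and diagonal kernel weights
#' `W`, `beta = (X'WX)^{-1} X'W y`. The coefficient covariance is the
#' heteroskedasticity-robust sandwich
#' `(X'WX)^{-1} X'W Sigma WX (X'WX)^{-1}` with `Sigma = diag(local
#' residuals^2)`.
#'
#' @param series An [observed_series()] or `data.frame(time, y)`.
#' @param t_star Evaluation time.
#' @param degree Local polynomial degree `p` (default 3).
#' @param kernel Kernel name, see [kernel_weight()].
#' @param bandwidth Positive bandwidth `h`.
#' @return List with `beta` (coefficients), `cov` (sandwich covariance),
#'   `hat_row` (influence of each observation on the local intercept).
#' @export
local_fit <- function(series, t_star, degree = 3,
                      kernel = "epanechnikov", bandwidth) {
  series <- as_series(series)
  if (bandwidth <= 0) stop("`bandwidth` must be positive")
  u <- abs(series$times - t_star) / bandwidth
  w <- kernel_weight(u, kernel)
  active <- w > 0
  if (sum(active) < degree + 1) {
    stop(sprintf("bandwidth too small at t* = %g: only %d observations with ",
                 t_star, sum(active)),
         "nonzero weight; need at least degree + 1")
  }
  tc <- series$times - t_star
  X <- outer(tc, 0:degree, `^`)
  WX <- X * w
  XtWX <- crossprod(X, WX)
  ok <- TRUE
  XtWXi <- tryCatch(solve(XtWX), error = function(e) {ok <<- FALSE; NULL})
  if (!ok || !all(is.finite(XtWXi)) ||
      rcond_est(XtWX) < 1e-12) {
    stop(sprintf("bandwidth too small at t* = %g: local system is rank ",
                 t_star), "deficient")
  }
  # rows of A map y to beta
  A <- XtWXi %*% t(WX)
  beta <- drop(A %*% series$y)
  resid <- series$y - drop(X %*% beta)
  Sigma_w <- (w * resid)^2                       # W Sigma W diagonal
  covb <- XtWXi %*% crossprod(X * Sigma_w, X) %*% XtWXi
  list(beta = beta, cov = covb, hat_row = A[1, ])
}

rcond_est <- function(m) {
  tryCatch(1 / kappa(m, exact = FALSE), error = function(e) 0)
}

# LOO-CV score for a fixed bandwidth via the hat-diagonal shortcut
# e_i / (1 - h_ii); Inf when any fit fails or a leverage reaches 1.
lpr_loo_score <- function(series, degree, kernel, h) {
  n <- length(series$times)
  hat_diag <- numeric(n)
  fit_vals <- numeric(n)
  for (i in seq_len(n)) {
    lf <- tryCatch(
      local_fit(series, series$times[i], degree, kernel, h),
      error = function(e) NULL
    )
    if (is.null(lf)) return(Inf)
    hat_diag[i] <- lf$hat_row[i]
    fit_vals[i] <- lf$beta[1]
  }
  if (any(hat_diag >= 1 - 1e-10)) return(Inf)
  mean(((series$y - fit_vals) / (1 - hat_diag))^2)
}

#' Data-driven bandwidth by leave-one-out cross-validation
#'
#' Evaluates the exact leave-one-out error of the local polynomial smoother
#' (via the hat-diagonal shortcut for linear smoothers) on a 30-point
#' log-spaced bandwidth grid from `2 * range/n` to `range`, and returns the
#' minimiser; under (numerical) ties the largest bandwidth wins, favouring
#' the smoother fit.
#'
#' @inheritParams local_fit
#' @param n_grid Number of candidate bandwidths.
#' @return The selected bandwidth (scalar).
#' @export
select_bandwidth <- function(series, degree = 3, kernel = "epanechnikov",
                             n_grid = 30) {
  series <- as_series(series)
  n <- length(series$times)
  if (n < degree + 2) stop("need at least degree + 2 observations")
  rng <- diff(range(series$times))
  grid <- exp(seq(log(2 * rng / n), log(rng), length.out = n_grid))
  scores <- vapply(grid, function(h) lpr_loo_score(series, degree, kernel, h),
                   numeric(1))
  if (all(!is.finite(scores))) {
    stop("no candidate bandwidth produced a full-rank fit")
  }
  best <- min(scores[is.finite(scores)])
  # largest h whose score is within numerical noise of the minimum
  tol <- max(1e-10, 1e-8 * abs(best))
  max(grid[is.finite(scores) & scores <= best + tol])
}

#' Local polynomial regression curve
#'
#' Fits the local polynomial smoother at each evaluation point and assembles
#' the unified [smoother_fit()]: estimates are the local intercepts, the hat
#' matrix rows are `e1' (X'WX)^{-1} X'W`, standard errors come from the local
#' sandwich covariance, and 95% intervals are `estimate +/- 1.96 * se`. No
#' boundary bandwidth inflation is applied.
#'
#' @inheritParams local_fit
#' @param bandwidth Positive bandwidth, or `"auto"` (default) for
#'   leave-one-out cross-validation via [select_bandwidth()].
#' @param eval_points Prediction times (default: the observation times).
#' @return A [smoother_fit()] with `wiggliness = c(bandwidth = h)`.
#' @examples
#' s <- observed_series(0:20, 2 * (0:20) + 1)
#' f <- lpr_fit(s, degree = 1, bandwidth = 5)
#' max(abs(f$estimate - s$y)) # ~0: degree-1 LPR reproduces a line
#' @export
lpr_fit <- function(series, degree = 3, kernel = "epanechnikov",
                    bandwidth = "auto", eval_points = NULL) {
  series <- as_series(series)
  if (is.null(eval_points)) eval_points <- series$times
  h <- if (identical(bandwidth, "auto")) {
    select_bandwidth(series, degree, kernel)
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  n_eval <- length(eval_points)
  n_obs <- length(series$times)
  est <- se <- numeric(n_eval)
  H <- matrix(0, n_eval, n_obs)
  for (j in seq_len(n_eval)) {
    lf <- local_fit(series, eval_points[j], degree, kernel, h)
    est[j] <- lf$beta[1]
    se[j] <- sqrt(max(0, lf$cov[1, 1]))
    H[j, ] <- lf$hat_row
  }
  smoother_fit(
    method = "lpr", eval_points = eval_points, estimate = est, se = se,
    lower = est - Z95 * se, upper = est + Z95 * se, hat = H,
    wiggliness = c(bandwidth = h), converged = TRUE,
    extra = list(degree = degree, kernel = kernel)
  )
}
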