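# Global polynomial regression baseline: OLS on raw (correlated) powers of
# standardized time, with per-dataset degree selection by GCV.

#' Global polynomial regression fit
#'
#' OLS on raw powers `1, t, ..., t^degree` of internally standardized time
#' (standardization keeps the raw-power design numerically manageable;
#' predictions are returned on the data scale). Pointwise 95% confidence
#' intervals use t-based standard errors, and the projection hat matrix is
#' returned for GCV scoring.
#'
#' @param series An [observed_series()] or `data.frame(time, y)`.
#' @param degree Polynomial degree, or `"auto"` (default) for GCV selection
#'   via [select_degree()].
#' @param max_degree Largest candidate degree in auto mode (default 10).
#' @param eval_points Prediction times (default: observation times).
#' @return A [smoother_fit()] with `wiggliness = c(degree = ...)`.
#' @examples
#' s <- observed_series(0:10, (0:10)^2)
#' f <- poly_fit(s, degree = 2)
#' max(abs(f$estimate - s$y)) # ~0
#' @export
poly_fit <- function(series, degree = "auto", max_degree = 10,
                     eval_points = NULL) {
  series <- as_series(series)
  if (identical(degree, "auto")) {
    degree <- select_degree(series, max_degree = max_degree)
  }
  n <- length(series$times)
  if (degree >= n) stop("degree too high for n: need degree < n_obs")
  mu_t <- mean(series$times)
  sd_t <- stats::sd(series$times)
  ts <- (series$times - mu_t) / sd_t
  X <- outer(ts, 0:degree, `^`)
  XtX <- crossprod(X)
  Mi <- tryCatch(solve(XtX), error = function(e) {
    stop("degree too high for n: design matrix numerically singular")
  })
  beta <- drop(Mi %*% crossprod(X, series$y))
  H <- X %*% Mi %*% t(X)
  fitted <- drop(X %*% beta)
  rss <- sum((series$y - fitted)^2)
  df_res <- n - (degree + 1)
  sigma2 <- if (df_res > 0) rss / df_res else 0
  if (is.null(eval_points)) eval_points <- series$times
  Xe <- outer((eval_points - mu_t) / sd_t, 0:degree, `^`)
  est <- drop(Xe %*% beta)
  se <- sqrt(pmax(0, sigma2 * rowSums((Xe %*% Mi) * Xe)))
  tq <- if (df_res > 0) stats::qt(0.975, df_res) else Z95
  He <- Xe %*% Mi %*% t(X)
  smoother_fit(
    method = "poly", eval_points = eval_points, estimate = est, se = se,
    lower = est - tq * se, upper = est + tq * se, hat = He,
    wiggliness = c(degree = degree), converged = TRUE,
    extra = list(coefficients = beta, sigma2 = sigma2, df_res = df_res)
  )
}

#' Select the polynomial degree by generalized cross-validation
#'
#' Minimises `GCV(d) = n * RSS(d) / (n - (d + 1))^2` over degrees
#' `1..max_degree`; under (numerical) ties the smallest degree wins,
#' guarding against overfitting.
#'
#' @inheritParams poly_fit
#' @return The selected degree (integer).
#' @export
select_degree <- function(series, max_degree = 10) {
  series <- as_series(series)
  n <- length(series$times)
  degrees <- seq_len(min(max_degree, n - 2))
  scores <- vapply(degrees, function(d) {
    f <- tryCatch(poly_fit(series, degree = d), error = function(e) NULL)
    if (is.null(f)) return(Inf)
    rss <- sum((series$y - f$estimate)^2)
    n * rss / (n - (d + 1))^2
  }, numeric(1))
  if (all(!is.finite(scores))) stop("no polynomial degree could be fitted")
  best <- min(scores[is.finite(scores)])
  tol <- max(1e-6 * abs(best), 1e-12 * n * stats::var(series$y))
  min(degrees[is.finite(scores) & scores <= best + tol])
}
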