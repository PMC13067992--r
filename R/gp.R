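# Gaussian-process regression with a zero-mean prior: closed-form posterior
# for fixed hyperparameters, and prior-regularised (MAP) or random-walk
# Metropolis estimation of (lengthscale rho, marginal SD alpha, noise SD
# sigma_n) on standardized data. The posterior mean is linear in y, so the
# hat matrix is exact.

GP_JITTER <- 1e-8

#' Gaussian-process covariance kernel matrix
#'
#' Covariance between function values at `times_a` and `times_b`:
#' squared exponential `alpha^2 * exp(-(ti - tj)^2 / (2 rho^2))`; dot product
#' `sigma_a^2 + sigma_b^2 * ti * tj` (a Bayesian linear regression in kernel
#' form); Matern 1/2 `alpha^2 * exp(-|ti - tj| / rho)`.
#'
#' @param times_a,times_b Numeric time vectors.
#' @param kernel `"sqexp"` (default), `"dot"` or `"matern12"`.
#' @param rho Characteristic lengthscale (> 0); wigglier processes have
#'   smaller lengthscales.
#' @param alpha Marginal standard deviation (> 0).
#' @param sigma_a,sigma_b Prior SDs of intercept and slope (dot kernel only).
#' @return `length(times_a)` x `length(times_b)` covariance matrix (no
#'   jitter; a `1e-8` diagonal jitter is added internally before any
#'   factorization).
#' @examples
#' gp_kernel_matrix(0, 1, "sqexp", rho = 1, alpha = 1) # exp(-0.5)
#' @export
gp_kernel_matrix <- function(times_a, times_b,
                             kernel = c("sqexp", "dot", "matern12"),
                             rho = 1, alpha = 1, sigma_a = 1, sigma_b = 1) {
  kernel <- match.arg(kernel)
  if (kernel != "dot" && (rho <= 0 || alpha <= 0)) {
    stop("hyperparameters `rho` and `alpha` must be positive")
  }
  if (kernel == "dot" && (sigma_a <= 0 || sigma_b <= 0)) {
    stop("hyperparameters `sigma_a` and `sigma_b` must be positive")
  }
  d <- outer(times_a, times_b, `-`)
  switch(kernel,
    sqexp = alpha^2 * exp(-d^2 / (2 * rho^2)),
    matern12 = alpha^2 * exp(-abs(d) / rho),
    dot = sigma_a^2 + sigma_b^2 * outer(times_a, times_b)
  )
}

# Cholesky of K + sigma_n^2 I with jitter; error if it fails even jittered.
gp_chol <- function(K, sigma_n) {
  n <- nrow(K)
  A <- K + diag(sigma_n^2 + GP_JITTER * max(diag(K)), n)
  tryCatch(chol(A), error = function(e) {
    stop("ill-conditioned kernel: Cholesky factorization failed after jitter")
  })
}

#' Log marginal likelihood of a GP regression
#'
#' `-0.5 y' (K + sigma_n^2 I)^{-1} y - 0.5 log|K + sigma_n^2 I| -
#' (n/2) log(2 pi)` for fixed hyperparameters, computed via Cholesky.
#'
#' @param series An [observed_series()] or `data.frame(time, y)`.
#' @inheritParams gp_kernel_matrix
#' @param sigma_n Observation noise SD (> 0).
#' @return Scalar log marginal likelihood.
#' @export
gp_log_marginal <- function(series, kernel = "sqexp", rho = 1, alpha = 1,
                            sigma_n = 1, sigma_a = 1, sigma_b = 1) {
  series <- as_series(series)
  if (sigma_n <= 0) stop("`sigma_n` must be positive")
  n <- length(series$times)
  K <- gp_kernel_matrix(series$times, series$times, kernel, rho, alpha,
                        sigma_a, sigma_b)
  L <- gp_chol(K, sigma_n)
  a <- backsolve(L, forwardsolve(t(L), series$y))
  -0.5 * sum(series$y * a) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
}

log_half_normal <- function(x, scale) {
  log(2) - log(scale) - 0.5 * log(2 * pi) - x^2 / (2 * scale^2)
}

# Penalised objective on theta = (log rho, log alpha, log sigma_n).
gp_map_objective <- function(theta, series, kernel, prior_sd) {
  h <- exp(theta)
  lml <- tryCatch(
    gp_log_marginal(series, kernel, rho = h[1], alpha = h[2],
                    sigma_n = h[3]),
    error = function(e) -Inf
  )
  lml + log_half_normal(h[1], prior_sd[1]) +
    log_half_normal(h[2], prior_sd[2]) +
    log_half_normal(h[3], prior_sd[3])
}

#' Estimate GP hyperparameters
#'
#' Default `"map"` mode maximises the log marginal likelihood plus half-normal
#' log-priors (SD 1 on the lengthscale, 5 on the marginal SD, 1 on the noise
#' SD; intended for standardized data) over `(log rho, log alpha,
#' log sigma_n)`, using Nelder-Mead from five dispersed starting points.
#' `"mcmc"` runs 4 random-walk Metropolis chains on the same posterior and
#' flags convergence by split R-hat < 1.05. `"fixed"` passes the supplied
#' values through unchanged.
#'
#' @inheritParams gp_log_marginal
#' @param estimation `"map"`, `"mcmc"` or `"fixed"`.
#' @param prior_sd_rho,prior_sd_alpha,prior_sd_noise Half-normal prior scales.
#' @param n_iter,n_warmup MCMC iterations and warmup per chain.
#' @return List with `rho`, `alpha`, `sigma_n`, `converged`, `objective`
#'   (penalised log marginal likelihood at the estimate), and for MCMC the
#'   post-warmup `samples` and `rhat`.
#' @export
gp_fit_hyperparameters <- function(series, kernel = "sqexp",
                                   estimation = c("map", "fixed", "mcmc"),
                                   rho = 1, alpha = 1, sigma_n = 1,
                                   prior_sd_rho = 1, prior_sd_alpha = 5,
                                   prior_sd_noise = 1,
                                   n_iter = 1000, n_warmup = 500) {
  estimation <- match.arg(estimation)
  series <- as_series(series)
  if (estimation == "fixed") {
    return(list(rho = rho, alpha = alpha, sigma_n = sigma_n,
                converged = TRUE, objective = NA_real_))
  }
  prior_sd <- c(prior_sd_rho, prior_sd_alpha, prior_sd_noise)
  starts <- rbind(
    log(c(0.2, 1.0, 0.5)),
    log(c(1.0, 1.0, 1.0)),
    log(c(0.5, 0.5, 0.2)),
    log(c(2.0, 2.0, 1.0)),
    log(c(0.1, 1.5, 0.8))
  )
  if (estimation == "map") {
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      opt <- tryCatch(
        stats::optim(starts[i, ], gp_map_objective, series = series,
                     kernel = kernel, prior_sd = prior_sd,
                     control = list(fnscale = -1, maxit = 500)),
        error = function(e) NULL
      )
      if (is.null(opt) || !is.finite(opt$value)) next
      if (is.null(best) || opt$value > best$value) best <- opt
    }
    if (is.null(best)) {
      return(list(rho = NA_real_, alpha = NA_real_, sigma_n = NA_real_,
                  converged = FALSE, objective = NA_real_))
    }
    h <- exp(best$par)
    return(list(rho = h[1], alpha = h[2], sigma_n = h[3], converged = TRUE,
                objective = best$value))
  }
  # mcmc: random-walk Metropolis on theta, 4 chains
  n_chains <- 4
  keep <- n_iter - n_warmup
  draws <- array(NA_real_, c(keep, n_chains, 3))
  for (ch in seq_len(n_chains)) {
    theta <- starts[ch, ]
    lp <- gp_map_objective(theta, series, kernel, prior_sd)
    step <- 0.15
    for (it in seq_len(n_iter)) {
      prop <- theta + stats::rnorm(3, 0, step)
      lp_prop <- gp_map_objective(prop, series, kernel, prior_sd)
      if (is.finite(lp_prop) && log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
      }
      if (it > n_warmup) draws[it - n_warmup, ch, ] <- theta
    }
  }
  rhat <- apply(draws, 3, split_rhat)
  med <- exp(apply(draws, 3, stats::median))
  list(rho = med[1], alpha = med[2], sigma_n = med[3],
       converged = all(rhat < 1.05), objective = NA_real_,
       samples = exp(matrix(draws, ncol = 3,
                            dimnames = list(NULL,
                                            c("rho", "alpha", "sigma_n")))),
       rhat = rhat)
}

# Split R-hat on an iterations x chains matrix of one parameter.
split_rhat <- function(x) {
  m <- nrow(x) %/% 2
  halves <- cbind(x[seq_len(m), , drop = FALSE],
                  x[m + seq_len(m), , drop = FALSE])
  chain_means <- colMeans(halves)
  chain_vars <- apply(halves, 2, stats::var)
  W <- mean(chain_vars)
  B <- m * stats::var(chain_means)
  if (W <= 0) return(1)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Closed-form GP posterior at fixed hyperparameters
#'
#' Posterior of the latent function given observations: mean
#' `K*' (K + sigma_n^2 I)^{-1} y`, variance `K** - K*' (K + sigma_n^2 I)^{-1}
#' K*`. With no observations the prior is returned (mean 0, variance
#' `alpha^2`).
#'
#' @inheritParams gp_log_marginal
#' @param eval_points Prediction times.
#' @return List with `mean`, `var` (latent-function variance), `var_obs`
#'   (latent variance plus `sigma_n^2`, for predicting observations), and
#'   `B`, the linear map from observations to posterior means.
#' @export
gp_posterior <- function(series = NULL, eval_points,
                         kernel = "sqexp", rho = 1, alpha = 1, sigma_n = 1,
                         sigma_a = 1, sigma_b = 1) {
  Kss_diag <- diag(gp_kernel_matrix(eval_points, eval_points, kernel, rho,
                                    alpha, sigma_a, sigma_b))
  if (is.null(series) || length(as_series(series)$times) == 0) {
    ne <- length(eval_points)
    return(list(mean = rep(0, ne), var = Kss_diag,
                var_obs = Kss_diag + sigma_n^2,
                B = matrix(0, ne, 0)))
  }
  series <- as_series(series)
  K <- gp_kernel_matrix(series$times, series$times, kernel, rho, alpha,
                        sigma_a, sigma_b)
  Ks <- gp_kernel_matrix(eval_points, series$times, kernel, rho, alpha,
                         sigma_a, sigma_b)
  L <- gp_chol(K, sigma_n)
  # B = Ks (K + sigma_n^2 I)^{-1}
  B <- t(backsolve(L, forwardsolve(t(L), t(Ks))))
  post_mean <- drop(B %*% series$y)
  V <- forwardsolve(t(L), t(Ks))                 # so t(V) %*% V = Ks A^-1 Ks'
  post_var <- pmax(0, Kss_diag - colSums(V^2))
  list(mean = post_mean, var = post_var, var_obs = post_var + sigma_n^2,
       B = B)
}

#' Gaussian-process regression fit
#'
#' Standardizes time and outcome (unless `standardize = FALSE`), resolves the
#' hyperparameters via [gp_fit_hyperparameters()], computes the closed-form
#' posterior, and destandardizes back to the data scale. The 95% band is the
#' credible band for the latent function (excluding observation noise). The
#' returned hat matrix includes the affine standardization, so
#' `estimate == hat %*% y` holds exactly.
#'
#' @inheritParams gp_fit_hyperparameters
#' @param eval_points Prediction times (default: observation times).
#' @param standardize Standardize predictor and outcome before estimation.
#'   Defaults to `TRUE` for `"map"`/`"mcmc"` (priors are set on the
#'   standardized scale) and `FALSE` for `"fixed"`, where supplied
#'   hyperparameters refer to the raw data scale.
#' @return A [smoother_fit()] with `wiggliness = c(lengthscale = rho)` (on the
#'   estimation scale) and the resolved hyperparameters in `$extra`.
#' @examples
#' s <- observed_series(c(0, 1), c(1, -1))
#' f <- gp_fit(s, estimation = "fixed", rho = 1, alpha = 1, sigma_n = 1)
#' round(f$estimate[1], 4) # 0.2824
#' @export
gp_fit <- function(series, kernel = c("sqexp", "dot", "matern12"),
                   estimation = c("map", "fixed", "mcmc"),
                   rho = 1, alpha = 1, sigma_n = 1,
                   sigma_a = 1, sigma_b = 1,
                   prior_sd_rho = 1, prior_sd_alpha = 5, prior_sd_noise = 1,
                   eval_points = NULL, standardize = NULL, ...) {
  kernel <- match.arg(kernel)
  estimation <- match.arg(estimation)
  series <- as_series(series)
  if (is.null(eval_points)) eval_points <- series$times
  if (is.null(standardize)) standardize <- estimation != "fixed"

  n <- length(series$times)
  if (standardize) {
    mu_t <- mean(series$times); sd_t <- stats::sd(series$times)
    mu_y <- mean(series$y); sd_y <- stats::sd(series$y)
    if (sd_t == 0 || sd_y == 0) stop("cannot standardize a degenerate series")
  } else {
    mu_t <- 0; sd_t <- 1; mu_y <- 0; sd_y <- 1
  }
  ts <- (series$times - mu_t) / sd_t
  ys <- (series$y - mu_y) / sd_y
  es <- (eval_points - mu_t) / sd_t
  std_series <- observed_series(ts, ys)

  hp <- if (estimation == "fixed") {
    list(rho = rho, alpha = alpha, sigma_n = sigma_n, converged = TRUE)
  } else {
    gp_fit_hyperparameters(std_series, kernel, estimation,
                           rho = rho, alpha = alpha, sigma_n = sigma_n,
                           prior_sd_rho = prior_sd_rho,
                           prior_sd_alpha = prior_sd_alpha,
                           prior_sd_noise = prior_sd_noise, ...)
  }
  if (!isTRUE(hp$converged) && is.na(hp$rho)) {
    ne <- length(eval_points)
    return(smoother_fit("gp", eval_points, rep(NA_real_, ne),
                        rep(NA_real_, ne), rep(NA_real_, ne),
                        rep(NA_real_, ne), hat = NULL,
                        wiggliness = c(lengthscale = NA_real_),
                        converged = FALSE))
  }
  post <- gp_posterior(std_series, es, kernel, rho = hp$rho,
                       alpha = hp$alpha, sigma_n = hp$sigma_n,
                       sigma_a = sigma_a, sigma_b = sigma_b)
  est <- mu_y + sd_y * post$mean
  se <- sd_y * sqrt(post$var)
  # absorb the y-standardization into the hat matrix:
  # est = B (y - mu_y 1) + mu_y 1 = [B + (1 - B 1) 1'/n] y
  H <- if (standardize) {
    post$B + outer(1 - rowSums(post$B), rep(1 / n, n))
  } else {
    post$B
  }
  smoother_fit(
    method = "gp", eval_points = eval_points, estimate = est, se = se,
    lower = est - Z95 * se, upper = est + Z95 * se, hat = H,
    wiggliness = c(lengthscale = hp$rho), converged = isTRUE(hp$converged),
    extra = list(hyperparameters = hp, kernel = kernel,
                 standardized = standardize,
                 scale = list(mu_t = mu_t, sd_t = sd_t,
                              mu_y = mu_y, sd_y = sd_y))
  )
}
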