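test_that("kernel matrices match their closed forms", {
  K <- gp_kernel_matrix(c(0, 1, 50), c(0, 1, 50), "sqexp", rho = 1,
                        alpha = 2)
  expect_equal(diag(K), rep(4, 3))
  expect_equal(K[1, 2], 4 * exp(-0.5))
  expect_lt(K[1, 3], 1e-12)
  expect_equal(gp_kernel_matrix(0, 1, "sqexp", rho = 1, alpha = 1)[1, 1],
               exp(-0.5))
  expect_equal(gp_kernel_matrix(2, 3, "dot", sigma_a = 1, sigma_b = 2)[1, 1],
               1 + 4 * 6)
  expect_equal(gp_kernel_matrix(0, 2, "matern12", rho = 2, alpha = 1)[1, 1],
               exp(-1))
  expect_error(gp_kernel_matrix(0, 1, "sqexp", rho = -1), "positive")
})

test_that("log marginal likelihood matches naive dense linear algebra", {
  # 1-point closed form: y = 0, K + sigma_n^2 = 2
  s1 <- observed_series(0, 0)
  expect_equal(gp_log_marginal(s1, rho = 1, alpha = 1, sigma_n = 1),
               -0.5 * log(2) - 0.5 * log(2 * pi))
  # 5-point series vs explicit inverse and determinant
  s <- make_sine_series(n = 5, span = 4, seed = 7)
  K <- gp_kernel_matrix(s$times, s$times, "sqexp", rho = 1.3, alpha = 0.8)
  A <- K + diag(0.6^2 + 1e-8 * max(diag(K)), 5)
  naive <- -0.5 * drop(t(s$y) %*% solve(A) %*% s$y) -
    0.5 * determinant(A)$modulus[1] - 2.5 * log(2 * pi)
  expect_equal(gp_log_marginal(s, rho = 1.3, alpha = 0.8, sigma_n = 0.6),
               naive, tolerance = 1e-8)
})

test_that("marginal likelihood of pure noise peaks at an interior sigma_n", {
  s <- make_noise_series(n = 60, seed = 3)
  grid <- seq(0.2, 3, by = 0.1)
  lml <- vapply(grid, function(sn) {
    gp_log_marginal(s, rho = 1, alpha = 0.3, sigma_n = sn)
  }, numeric(1))
  i <- which.max(lml)
  expect_gt(i, 1)
  expect_lt(i, length(grid))
  expect_lt(abs(grid[i] - 1), 0.4)   # true noise SD is 1
})

test_that("posterior matches the 2x2 linear-solve oracle", {
  s <- observed_series(c(0, 1), c(1, -1))
  post <- gp_posterior(s, eval_points = 0, rho = 1, alpha = 1, sigma_n = 1)
  k <- exp(-0.5)
  A <- matrix(c(2, k, k, 2), 2) + diag(1e-8, 2)
  oracle <- drop(c(1, k) %*% solve(A, c(1, -1)))
  expect_equal(post$mean, oracle, tolerance = 1e-8)
  expect_equal(round(post$mean, 4), 0.2824)
  v_oracle <- 1 - drop(c(1, k) %*% solve(A, c(1, k)))
  expect_equal(post$var, v_oracle, tolerance = 1e-6)
})

test_that("with no observations the posterior is the prior", {
  post <- gp_posterior(NULL, eval_points = c(0, 5), rho = 1, alpha = 1.5,
                       sigma_n = 1)
  expect_equal(post$mean, c(0, 0))
  expect_equal(post$var, c(2.25, 2.25))
})

test_that("a vanishing noise SD interpolates the observations", {
  s <- make_sine_series(n = 8, span = 6, noise_sd = 0)
  post <- gp_posterior(s, eval_points = s$times, rho = 2, alpha = 2,
                       sigma_n = 1e-10)
  expect_lt(max(abs(post$mean - s$y)), 1e-5)
})

test_that("posterior variance never exceeds prior variance", {
  s <- make_sine_series(n = 20)
  eval_pts <- seq(-2, 12, length.out = 30)
  post <- gp_posterior(s, eval_pts, rho = 1.5, alpha = 1.2, sigma_n = 0.5)
  expect_true(all(post$var <= 1.2^2 + 1e-10))
})

test_that("dot-kernel GP equals Bayesian linear regression in closed form", {
  s <- make_sine_series(n = 12, span = 3, seed = 9)
  sa <- 2; sb <- 1.5; sn <- 0.7
  post <- gp_posterior(s, s$times, kernel = "dot", sigma_n = sn,
                       sigma_a = sa, sigma_b = sb)
  # ridge/Bayesian regression on (1, t) with prior variances (sa^2, sb^2)
  X <- cbind(1, s$times)
  P <- diag(c(1 / sa^2, 1 / sb^2))
  beta <- solve(crossprod(X) / sn^2 + P, crossprod(X, s$y) / sn^2)
  expect_equal(post$mean, drop(X %*% beta), tolerance = 1e-6)
})

test_that("fixed-mode hyperparameter resolution is a passthrough", {
  s <- make_sine_series(n = 10)
  hp <- gp_fit_hyperparameters(s, estimation = "fixed", rho = 3, alpha = 2,
                               sigma_n = 0.4)
  expect_equal(hp[c("rho", "alpha", "sigma_n")],
               list(rho = 3, alpha = 2, sigma_n = 0.4))
  expect_true(hp$converged)
})

test_that("on white noise the signal SD shrinks below the noise SD", {
  s <- make_noise_series(n = 80, seed = 6)
  f <- gp_fit(s, estimation = "map")  # standardizes before applying priors
  hp <- f$extra$hyperparameters
  expect_true(hp$converged)
  expect_lt(hp$alpha, hp$sigma_n)
})

test_that("standardize/destandardize round trip is exact for the fit", {
  s <- make_sine_series(n = 30, amp = 20, noise_sd = 2, seed = 5)
  f <- gp_fit(s, estimation = "fixed", rho = 1.5, alpha = 1, sigma_n = 0.3,
              standardize = TRUE)
  # hat identity holds through the affine destandardization
  expect_equal(drop(f$hat %*% s$y), f$estimate, tolerance = 1e-8)
  # manual destandardization reproduces the estimate
  ts <- (s$times - mean(s$times)) / sd(s$times)
  ys <- (s$y - mean(s$y)) / sd(s$y)
  post <- gp_posterior(observed_series(ts, ys), ts, rho = 1.5, alpha = 1,
                       sigma_n = 0.3)
  expect_equal(f$estimate, mean(s$y) + sd(s$y) * post$mean,
               tolerance = 1e-10)
  expect_equal(f$se, sd(s$y) * sqrt(post$var), tolerance = 1e-10)
})

test_that("MCMC mode runs, mixes and returns samples", {
  s <- make_sine_series(n = 25, seed = 8)
  f <- gp_fit(s, estimation = "mcmc", n_iter = 400, n_warmup = 200)
  hp <- f$extra$hyperparameters
  expect_equal(nrow(hp$samples), 4 * 200)
  expect_true(all(hp$samples > 0))
  expect_length(hp$rhat, 3)
  expect_true(is.finite(f$estimate[1]))
})
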