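# Shared fixtures, all generated in code under fixed seeds.

# Smooth sine with Gaussian noise.
make_sine_series <- function(n = 50, span = 10, amp = 2, period = 5,
                             noise_sd = 0.3, seed = 42) {
  withr::with_seed(seed, {
    t <- seq(0, span, length.out = n)
    f <- amp * sin(2 * pi * t / period)
    observed_series(t, f + rnorm(n, 0, noise_sd), latent = f)
  })
}

make_noise_series <- function(n = 40, span = 10, seed = 42) {
  withr::with_seed(seed, {
    t <- seq(0, span, length.out = n)
    observed_series(t, rnorm(n), latent = rep(0, n))
  })
}

make_poly_series <- function(coefs, n = 30, span = 6) {
  t <- seq(0, span, length.out = n)
  f <- drop(outer(t, seq_along(coefs) - 1, `^`) %*% coefs)
  observed_series(t, f, latent = f)
}

# One draw of latent f and noisy y from a squared-exponential GP prior.
draw_gp_prior <- function(times, rho = 1, alpha = 1, sigma_n = 1, seed = 1) {
  withr::with_seed(seed, {
    K <- gp_kernel_matrix(times, times, "sqexp", rho = rho, alpha = alpha)
    L <- chol(K + diag(1e-8, length(times)))
    f <- drop(crossprod(L, rnorm(length(times))))
    observed_series(times, f + sigma_n * rnorm(length(times)), latent = f)
  })
}

# Dense weighted least squares oracle: beta = (X'WX)^{-1} X'W y.
wls_oracle <- function(t, y, t_star, degree, w) {
  X <- outer(t - t_star, 0:degree, `^`)
  solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% y)
}
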