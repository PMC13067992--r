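# helper: wrap a hand-built linear smoother as a smoother_fit
manual_fit <- function(times, y, H, method = "manual") {
  est <- drop(H %*% y)
  smoother_fit(method, times, est, rep(0, length(est)), est, est,
               hat = H, wiggliness = c(value = NA_real_))
}

test_that("MSE matches its arithmetic definition", {
  s <- observed_series(1:3, c(1, 2, 3), latent = c(1, 1, 1))
  f <- manual_fit(1:3, s$y, diag(3))
  expect_equal(mse(f, s), 5 / 3)
  f0 <- manual_fit(1:3, s$latent, diag(3))
  expect_equal(mse(f0, s), 0)
  s1 <- observed_series(1:3, s$latent + 1, latent = c(1, 1, 1))
  expect_equal(mse(manual_fit(1:3, s1$y, diag(3)), s1), 1)
})

test_that("GCV of the intercept-only smoother equals its closed form and LOO", {
  y <- c(1, 2, 3)
  s <- observed_series(1:3, y)
  H <- matrix(1 / 3, 3, 3)
  f <- manual_fit(1:3, y, H)
  expect_equal(gcv_score(f, s), 3 * 2 / (3 - 1)^2)  # RSS = 2
  loo <- vapply(1:3, function(i) (y[i] - mean(y[-i]))^2, numeric(1))
  expect_equal(gcv_score(f, s), mean(loo), tolerance = 1e-12)
})

test_that("GCV equals explicit-refit LOO for balanced constant-leverage OLS", {
  withr::with_seed(1, {
    g <- rep(1:3, each = 4)
    y <- rnorm(12, mean = g)
  })
  s <- observed_series(1:12, y)
  X <- model.matrix(~ factor(g))
  H <- X %*% solve(crossprod(X), t(X))
  f <- manual_fit(1:12, y, H)
  # explicit refit: prediction for the left-out point is its group mean
  # computed without it
  loo <- vapply(1:12, function(i) {
    (y[i] - mean(y[-i][g[-i] == g[i]]))^2
  }, numeric(1))
  expect_equal(gcv_score(f, s), mean(loo), tolerance = 1e-10)
})

test_that("hat-diagonal LOO shortcut equals explicit refitting for a ridge", {
  s <- make_sine_series(n = 20, seed = 12)
  b <- build_basis(s$times, K = 8)
  lambda <- 2.5
  pf <- fit_penalized(s, lambda, basis = b)
  shortcut <- ((s$y - pf$fitted) / (1 - diag(pf$hat)))^2
  explicit <- vapply(seq_along(s$y), function(i) {
    Xi <- b$X[-i, , drop = FALSE]
    beta <- solve(crossprod(Xi) + lambda * b$S, crossprod(Xi, s$y[-i]))
    (s$y[i] - drop(b$X[i, ] %*% beta))^2
  }, numeric(1))
  expect_equal(shortcut, explicit, tolerance = 1e-8)
})

test_that("interpolating fits make the GCV undefined", {
  withr::with_seed(2, s <- observed_series(1:4, rnorm(4)))
  f <- manual_fit(1:4, s$y, diag(4))
  expect_error(gcv_score(f, s), "undefined")
})

test_that("coverage scores the latent process against the bands", {
  s <- observed_series(1:4, rnorm(4), latent = c(0, 0, 0, 0))
  wide <- smoother_fit("m", 1:4, rep(1, 4), rep(1, 4), rep(-Inf, 4),
                       rep(Inf, 4), NULL, c(v = 1))
  expect_equal(ci_coverage(wide, s), 1)
  zero <- smoother_fit("m", 1:4, rep(5, 4), rep(0, 4), rep(5, 4), rep(5, 4),
                       NULL, c(v = 1))
  expect_equal(ci_coverage(zero, s), 0)
})

test_that("Monte-Carlo standard errors follow the binomial benchmark", {
  rec <- data.frame(method = "gam", process = "logistic",
                    coverage = rep(0.9, 50), mse = rep(1, 50))
  out <- mc_standard_error(rec)
  expect_equal(unname(out$max_se["coverage"]), 0)
  withr::with_seed(3, {
    cov <- rbinom(100, 20, 0.9) / 20    # per-replicate mean coverages
    rec2 <- data.frame(method = "gam", process = "x", coverage = cov)
    out2 <- mc_standard_error(rec2)
    expect_equal(unname(out2$max_se["coverage"]),
                 sqrt(0.9 * 0.1 / 20) / sqrt(100), tolerance = 0.35)
    # doubling the replicates shrinks the SE by about sqrt(2)
    cov4 <- rbinom(400, 20, 0.9) / 20
    rec4 <- data.frame(method = "gam", process = "x", coverage = cov4)
    out4 <- mc_standard_error(rec4)
    ratio <- out2$max_se["coverage"] / out4$max_se["coverage"]
    expect_gt(ratio, 1.5)
    expect_lt(ratio, 2.9)
  })
})

test_that("partial eta-squared matches a hand-computed 2x2 decomposition", {
  rec <- expand.grid(method = c("a", "b"), process = c("p", "q"),
                     replicate = 1:2)
  rec$mse <- c(1, 3, 2, 6, 1.4, 3.4, 2.4, 6.4)
  tab <- anova_partial_eta2(rec, "mse", factors = c("method", "process"))
  # hand decomposition (balanced: type-I == type-III)
  gm <- mean(rec$mse)
  ss_a <- sum(tapply(rec$mse, rec$method, function(v) {
    length(v) * (mean(v) - gm)^2
  }))
  ss_b <- sum(tapply(rec$mse, rec$process, function(v) {
    length(v) * (mean(v) - gm)^2
  }))
  cellm <- with(rec, tapply(mse, interaction(method, process), mean))
  ss_cells <- 2 * sum((cellm - gm)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_res <- sum((rec$mse - ave(rec$mse,
                               interaction(rec$method, rec$process)))^2)
  expect_equal(tab$sum_sq, c(ss_a, ss_b, ss_ab), tolerance = 1e-10)
  expect_equal(tab$partial_eta2,
               c(ss_a, ss_b, ss_ab) / (c(ss_a, ss_b, ss_ab) + ss_res),
               tolerance = 1e-10)
})

test_that("partial eta-squared is bounded and affine-invariant", {
  withr::with_seed(4, {
    rec <- expand.grid(method = c("a", "b"), process = c("p", "q"),
                       replicate = 1:5)
    rec$mse <- rnorm(nrow(rec), mean = as.integer(rec$method == "a"))
  })
  t1 <- anova_partial_eta2(rec, "mse", factors = c("method", "process"))
  expect_true(all(t1$partial_eta2 >= 0 & t1$partial_eta2 <= 1))
  rec2 <- rec
  rec2$mse <- 100 * rec$mse - 7
  t2 <- anova_partial_eta2(rec2, "mse", factors = c("method", "process"))
  expect_equal(t1$partial_eta2, t2$partial_eta2, tolerance = 1e-10)
})

test_that("degenerate ANOVA cases behave as expected", {
  rec <- expand.grid(method = c("a", "b"), replicate = 1:3)
  rec$mse <- 2
  tab <- anova_partial_eta2(rec, "mse", factors = "method")
  expect_equal(tab$partial_eta2, 0)
  rec$mse <- ifelse(rec$method == "a", 1, 5)  # zero within-group variance
  tab2 <- anova_partial_eta2(rec, "mse", factors = "method")
  expect_equal(tab2$partial_eta2, 1)
  # crossing with a missing (method, process) combination is refused
  rec3 <- expand.grid(method = c("a", "b"), process = c("p", "q"),
                      replicate = 1:2)
  rec3$mse <- seq_len(nrow(rec3))
  rec3 <- rec3[!(rec3$method == "b" & rec3$process == "q"), ]
  expect_error(
    anova_partial_eta2(rec3, "mse", factors = c("method", "process")),
    "empty"
  )
})

test_that("dropping non-converged records is pure filtering", {
  rec <- expand.grid(method = c("a", "b"), replicate = 1:4)
  withr::with_seed(5, rec$mse <- rnorm(8, as.integer(rec$method == "a")))
  rec$converged <- TRUE
  full <- anova_partial_eta2(rec, "mse", factors = "method")
  rec2 <- rbind(rec, data.frame(method = "a", replicate = 9,
                                mse = 1e6, converged = FALSE))
  filtered <- anova_partial_eta2(rec2, "mse", factors = "method")
  expect_equal(full, filtered)
})

test_that("the EDF screen separates linear from wiggly synthetic persons", {
  # GCV-selected smooths fit spurious wiggle on some purely linear series
  # (an independent implementation, mgcv, does the same on identical data),
  # so the screen is assessed on separation and on agreement with mgcv.
  lin_edf <- vapply(1:20, function(i) {
    f <- gam_fit(simulate_person("linear", seed = i))
    unname(f$wiggliness[["edf"]])
  }, numeric(1))
  wig_edf <- vapply(1:20, function(i) {
    f <- gam_fit(simulate_person("wiggly", seed = i))
    unname(f$wiggliness[["edf"]])
  }, numeric(1))
  cls_lin <- classify_idiographic(lin_edf)
  cls_wig <- classify_idiographic(wig_edf)
  expect_gte(cls_wig$counts[["nonlinear"]], 18)
  expect_gt(cls_lin$counts[["linear"]], cls_wig$counts[["linear"]])
  expect_lt(median(lin_edf), median(wig_edf))
  # infinite threshold: everything is linear
  expect_equal(classify_idiographic(wig_edf, threshold = Inf)$counts[["linear"]],
               20)
  expect_error(classify_idiographic(c(1, NA)), "missing")

  skip_if_not_installed("mgcv")
  mgcv_lin <- vapply(1:20, function(i) {
    s <- simulate_person("linear", seed = i)
    g <- mgcv::gam(y ~ s(time, bs = "tp", k = 10),
                   data = data.frame(time = s$times, y = s$y))
    summary(g)$edf
  }, numeric(1))
  n_mgcv <- sum(mgcv_lin < 1.001)
  expect_lte(abs(cls_lin$counts[["linear"]] - n_mgcv), 3)
})
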