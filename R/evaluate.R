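# Scoring and summarisation: MSE against the latent truth, hat-matrix GCV,
# 95% interval coverage of the latent process, Monte-Carlo standard errors,
# partial eta-squared ANOVA summaries of the factorial results, and the
# idiographic EDF screen.

#' Mean squared error against the latent truth
#'
#' Mean over the observation times of the squared difference between the
#' smoother's estimate and the true (generated) latent process value.
#'
#' @param fit A [smoother_fit()] evaluated at the observation times.
#' @param series An [observed_series()] carrying the latent truth.
#' @return Scalar MSE (outcome units squared).
#' @export
mse <- function(fit, series) {
  series <- as_series(series)
  if (is.null(series$latent)) stop("series carries no latent truth")
  check_eval_alignment(fit, series)
  mean((fit$estimate - series$latent)^2)
}

check_eval_alignment <- function(fit, series) {
  if (length(fit$eval_points) != length(series$times) ||
      any(abs(fit$eval_points - series$times) > 1e-8)) {
    stop("fit evaluation points are not aligned with the observation times")
  }
  invisible(TRUE)
}

#' Generalized cross-validation score of a fitted smoother
#'
#' `GCV = n * RSS / (n - trace(H))^2`, with the hat matrix `H` taken at the
#' tuning values the method selected on the full sample (bandwidth, GP
#' hyperparameters, lambda, degree) and then held fixed — an analytic
#' surrogate for leave-one-out cross-validation that avoids refitting.
#'
#' @inheritParams mse
#' @return Scalar GCV.
#' @export
gcv_score <- function(fit, series) {
  series <- as_series(series)
  check_eval_alignment(fit, series)
  if (is.null(fit$hat)) stop("fit carries no hat matrix; GCV undefined")
  H <- fit$hat
  if (nrow(H) != ncol(H)) stop("hat matrix must be square at the obs times")
  n <- length(series$y)
  tr_h <- sum(diag(H))
  if (tr_h >= n - 1e-10) {
    stop("GCV undefined: trace(H) >= n (interpolating fit)")
  }
  rss <- sum((series$y - fit$estimate)^2)
  n * rss / (n - tr_h)^2
}

#' 95% interval coverage of the latent process
#'
#' Proportion of observation times at which the true latent value lies inside
#' the fit's 95% confidence/credible band.
#'
#' @inheritParams mse
#' @return Proportion in `[0, 1]`.
#' @export
ci_coverage <- function(fit, series) {
  series <- as_series(series)
  if (is.null(series$latent)) stop("series carries no latent truth")
  check_eval_alignment(fit, series)
  mean(fit$lower <= series$latent & series$latent <= fit$upper)
}

#' Monte-Carlo standard errors of simulation outcomes
#'
#' For each condition-by-method group, the standard error of the replicate
#' mean, `sd / sqrt(m)`, for each outcome column; also reports the maximum
#' across groups per outcome (the figure usually quoted for a simulation
#' study).
#'
#' @param records Data frame of per-replicate scores (as produced by
#'   [run_study()]), with outcome columns among `mse`, `gcv`, `coverage`.
#' @param group_vars Character vector of grouping columns (default: method
#'   and all design factors present).
#' @return List with `by_group` (data frame of per-group SEs) and `max_se`
#'   (named vector of maxima per outcome).
#' @export
mc_standard_error <- function(records,
                              group_vars = intersect(
                                c("method", "process", "dev", "period",
                                  "frequency"), names(records))) {
  outcomes <- intersect(c("mse", "gcv", "coverage"), names(records))
  if (length(outcomes) == 0) stop("no outcome columns found")
  key <- interaction(records[group_vars], drop = TRUE)
  if (any(tabulate(key) < 2)) {
    stop("need at least 2 replicates per group for a Monte-Carlo SE")
  }
  se_fun <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 2) return(NA_real_)
    stats::sd(x) / sqrt(length(x))
  }
  by_group <- do.call(rbind, lapply(split(records, key), function(g) {
    out <- g[1, group_vars, drop = FALSE]
    for (o in outcomes) out[[paste0("se_", o)]] <- se_fun(g[[o]])
    out
  }))
  rownames(by_group) <- NULL
  max_se <- vapply(outcomes, function(o) {
    max(by_group[[paste0("se_", o)]], na.rm = TRUE)
  }, numeric(1))
  list(by_group = by_group, max_se = max_se)
}

#' Factorial ANOVA with partial eta-squared effect sizes
#'
#' Fits a fully crossed fixed-effects ANOVA (type-I sums of squares, all main
#' and interaction effects) of one simulation outcome on the design factors,
#' and reports `partial eta^2 = SS_effect / (SS_effect + SS_residual)` per
#' effect. Non-converged records are dropped before fitting.
#'
#' @param records Data frame of per-replicate scores (see [run_study()]).
#' @param outcome `"mse"` or `"gcv"`.
#' @param factors Design factor columns (defaults to those present among
#'   method, process, period, frequency, dev).
#' @return Data frame with columns `effect`, `df`, `sum_sq`, `partial_eta2`.
#' @export
anova_partial_eta2 <- function(records, outcome = c("mse", "gcv"),
                               factors = intersect(
                                 c("method", "process", "period",
                                   "frequency", "dev"), names(records))) {
  outcome <- match.arg(outcome)
  if (!outcome %in% names(records)) stop("outcome column not found")
  if ("converged" %in% names(records)) {
    records <- records[records$converged %in% TRUE, , drop = FALSE]
  }
  records <- records[!is.na(records[[outcome]]), , drop = FALSE]
  for (f in factors) {
    records[[f]] <- factor(records[[f]])
    if (nlevels(records[[f]]) < 2) {
      stop("factor `", f, "` has fewer than 2 levels after filtering")
    }
  }
  cells <- interaction(records[factors], drop = FALSE)
  empty <- setdiff(levels(cells), levels(droplevels(cells)))
  if (length(empty) > 0) {
    stop("empty design cells: ", paste(utils::head(empty, 5), collapse = ", "))
  }
  fml <- stats::as.formula(
    paste(outcome, "~", paste(factors, collapse = " * ")))
  fit <- stats::aov(fml, data = records)
  tab <- summary(fit)[[1]]
  effects <- trimws(rownames(tab))
  ss <- tab[["Sum Sq"]]
  df <- tab[["Df"]]
  is_res <- effects == "Residuals"
  ss_res <- ss[is_res]
  peta <- ss[!is_res] / (ss[!is_res] + ss_res)
  # a constant outcome has no variance to attribute: all effects are null
  y <- records[[outcome]]
  if (stats::var(y) <= 1e-14 * (mean(y)^2 + 1)) peta <- rep(0, sum(!is_res))
  out <- data.frame(
    effect = effects[!is_res], df = df[!is_res], sum_sq = ss[!is_res],
    partial_eta2 = peta,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify idiographic trends by effective degrees of freedom
#'
#' A per-person GAM smooth with `EDF < threshold` is classified as an
#' effectively linear trend; larger EDF as non-linear (wiggly).
#'
#' @param fits A list of per-person [gam_fit()] results, or a numeric vector
#'   of EDF values.
#' @param threshold Classification threshold (default 1.001).
#' @return List with `counts` (named vector `linear`, `nonlinear`), `edf`
#'   (the EDF values), and `linear` (logical vector).
#' @export
classify_idiographic <- function(fits, threshold = 1.001) {
  edf <- if (is.numeric(fits)) {
    fits
  } else {
    vapply(fits, function(f) {
      w <- f$wiggliness
      if (!("edf" %in% names(w))) stop("fit carries no EDF")
      unname(w[["edf"]])
    }, numeric(1))
  }
  if (anyNA(edf)) stop("missing EDF values")
  linear <- edf < threshold
  list(counts = c(linear = sum(linear), nonlinear = sum(!linear)),
       edf = edf, linear = linear)
}
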