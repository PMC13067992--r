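#' Construct an observed series
#'
#' Bundles observation times, noisy observations and (when known, i.e. for
#' simulated data) the aligned latent truth into the container that all
#' smoothers and scoring functions consume.
#'
#' @param times Numeric vector of observation times, strictly increasing.
#' @param y Numeric vector of observed values, same length as `times`.
#' @param latent Optional numeric vector of true latent process values at
#'   `times`; `NULL` for real data.
#' @param dynamic_error_variance Optional scalar recording the dynamic-error
#'   variance condition the series was generated under.
#' @return An object of class `observed_series`: a list with elements
#'   `times`, `y`, `latent`, `dynamic_error_variance`.
#' @examples
#' s <- observed_series(0:10, sin(0:10))
#' print(s)
#' @export
observed_series <- function(times, y, latent = NULL,
                            dynamic_error_variance = NULL) {
  times <- as.numeric(times)
  y <- as.numeric(y)
  if (length(times) != length(y)) {
    stop("`times` and `y` must have the same length")
  }
  if (anyNA(times) || anyNA(y) || any(!is.finite(times)) || any(!is.finite(y))) {
    stop("`times` and `y` must be finite and non-missing")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing")
  }
  if (!is.null(latent)) {
    latent <- as.numeric(latent)
    if (length(latent) != length(times)) {
      stop("`latent` must have the same length as `times`")
    }
  }
  structure(
    list(times = times, y = y, latent = latent,
         dynamic_error_variance = dynamic_error_variance),
    class = "observed_series"
  )
}

#' @export
print.observed_series <- function(x, ...) {
  cat(sprintf("<observed_series> n = %d, t in [%g, %g]%s\n",
              length(x$times), min(x$times), max(x$times),
              if (is.null(x$latent)) "" else ", latent truth attached"))
  invisible(x)
}

#' @export
length.observed_series <- function(x) length(x$times)

# Coerce data.frame (time, y[, latent]) or observed_series; used by all fitters.
as_series <- function(x) {
  if (inherits(x, "observed_series")) return(x)
  if (is.data.frame(x)) {
    nm <- names(x)
    tcol <- intersect(c("time", "times", "t"), nm)[1]
    ycol <- intersect(c("y", "value"), nm)[1]
    if (is.na(tcol) || is.na(ycol)) {
      stop("data frame must have columns `time` and `y`")
    }
    latent <- if ("latent" %in% nm) x[["latent"]] else NULL
    return(observed_series(x[[tcol]], x[[ycol]], latent = latent))
  }
  stop("cannot interpret input as an observed series; supply an ",
       "`observed_series` or a data frame with columns `time` and `y`")
}

#' Read / write an observed series as CSV
#'
#' The on-disk format is a plain CSV with header `time,y` and, when the latent
#' truth is known, a third column `latent`.
#'
#' @param path File path.
#' @rdname series_io
#' @return `read_series` returns an `observed_series`; `write_series` returns
#'   `path` invisibly.
#' @export
read_series <- function(path) {
  df <- utils::read.csv(path)
  as_series(df)
}

#' @param series An `observed_series`.
#' @rdname series_io
#' @export
write_series <- function(series, path) {
  series <- as_series(series)
  df <- data.frame(time = series$times, y = series$y)
  if (!is.null(series$latent)) df$latent <- series$latent
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a smoother fit
#'
#' Unified return value of [lpr_fit()], [gp_fit()], [gam_fit()] and
#' [poly_fit()]: pointwise estimates with standard errors and 95% intervals,
#' the hat (influence) matrix mapping observations to predictions, and a
#' method-specific wiggliness summary (bandwidth for LPR, lengthscale for GP,
#' effective degrees of freedom for the GAM, degree for the polynomial).
#'
#' @param method Character label.
#' @param eval_points Numeric vector of prediction times.
#' @param estimate,se Pointwise estimate and standard error at `eval_points`.
#' @param lower,upper 95% interval bounds.
#' @param hat Numeric matrix, `length(eval_points)` x n_obs, with
#'   `estimate == hat %*% y` for these linear smoothers.
#' @param wiggliness Named scalar (or small list) summarising wiggliness.
#' @param converged Logical convergence flag.
#' @param extra Optional list of method-specific detail kept alongside.
#' @return An object of class `smoother_fit`.
#' @export
smoother_fit <- function(method, eval_points, estimate, se, lower, upper,
                         hat, wiggliness, converged = TRUE, extra = list()) {
  n_eval <- length(eval_points)
  stopifnot(length(estimate) == n_eval, length(se) == n_eval,
            length(lower) == n_eval, length(upper) == n_eval)
  if (!is.null(hat) && nrow(hat) != n_eval) {
    stop("hat matrix must have one row per eval point")
  }
  if (isTRUE(any(lower > estimate + 1e-8, na.rm = TRUE)) ||
      isTRUE(any(upper < estimate - 1e-8, na.rm = TRUE))) {
    stop("interval bounds must bracket the estimate")
  }
  structure(
    list(method = method, eval_points = eval_points,
         estimate = as.numeric(estimate), se = as.numeric(se),
         lower = as.numeric(lower), upper = as.numeric(upper),
         hat = hat, wiggliness = wiggliness,
         converged = isTRUE(converged), extra = extra),
    class = "smoother_fit"
  )
}

#' @export
print.smoother_fit <- function(x, ...) {
  wl <- paste(names(x$wiggliness), signif(unlist(x$wiggliness), 4),
              sep = " = ", collapse = ", ")
  cat(sprintf("<smoother_fit: %s> %d eval points; %s; converged: %s\n",
              x$method, length(x$eval_points), wl, x$converged))
  invisible(x)
}

#' @export
fitted.smoother_fit <- function(object, ...) object$estimate

# z quantile for the 95% pointwise bands used throughout.
Z95 <- 1.96
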