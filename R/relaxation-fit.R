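# Single-parameter exponential relaxation fit of the approach response. The
# attracted fish returns from the attracted distance y0 toward the baseline
# y_eq as y(t) = (y0 - y_eq) * exp(-k (t - t0)) + y_eq; k is the only free
# parameter and 1/k is the retention time of the attraction.

#' Fit the exponential relaxation rate of an approach response
#'
#' Least-squares fit of the single free parameter k to the group-mean
#' distance series on t >= t0, with t0, y0 and y_eq supplied as fixed model
#' constants shared across stimuli (t0 the most-attracted time, y0 the
#' minimum distance, y_eq the pre-stimulus mean). The curve satisfies
#' y(t0) = y0 and y(Inf) = y_eq. The standard error of k comes from the
#' usual nonlinear least-squares linearization, inflated by the AR(1)
#' equivalent-sample-size factor sqrt((1 + rho)/(1 - rho)) with rho the
#' lag-1 residual autocorrelation, since binned behavioural series remain
#' serially correlated; the confidence interval on
#' the retention time 1/k uses the delta method, optionally with a
#' Bonferroni-corrected level for `bonferroni_m` simultaneous comparisons
#' (6 for the pairwise comparisons of four stimuli). A fit driven to k = 0
#' (no relaxation) is flagged as having unbounded retention.
#'
#' @param t time, seconds (e.g. 1-s bin centres from [mean_y_series()]).
#' @param y mean distance, mm, same length as `t`.
#' @param t0 start of relaxation, seconds.
#' @param y0 distance at `t0`, mm.
#' @param y_eq equilibrium distance, mm.
#' @param conf_level confidence level before Bonferroni correction.
#' @param bonferroni_m number of simultaneous comparisons (1 = none).
#' @param k_max upper bound of the rate search, 1/s.
#' @return an object of class `relaxation_fit` with components `k`, `se_k`,
#'   `k_ci`, `retention` (1/k, s), `retention_ci`, `unbounded`, the model
#'   constants, `fitted`, `residuals` and the fitting window data.
#' @seealso [retention_time()], [predict.relaxation_fit()]
#' @export
fit_relaxation <- function(t, y, t0 = 77, y0 = 10, y_eq = 41,
                           conf_level = 0.95, bonferroni_m = 1, k_max = 10) {
  stopifnot(length(t) == length(y), all(is.finite(t)), all(is.finite(y)),
            conf_level > 0, conf_level < 1, bonferroni_m >= 1, k_max > 0)
  sel <- t >= t0
  if (sum(sel) < 3) stop("series does not cover [t0, session end]")
  ti <- t[sel] - t0
  yi <- y[sel]
  a <- y0 - y_eq
  sse <- function(k) sum((yi - (a * exp(-k * ti) + y_eq))^2)
  opt <- optimize(sse, c(0, k_max), tol = 1e-10)
  k <- opt$minimum
  if (sse(0) <= opt$objective) k <- 0
  unbounded <- k < 1e-4     # retention beyond ~3 h: no relaxation resolved
  fit <- a * exp(-k * ti) + y_eq
  res <- yi - fit
  n <- length(yi)
  sigma2 <- sum(res^2) / (n - 1)
  g <- -a * ti * exp(-k * ti)
  se_k <- if (sum(g^2) > 0) sqrt(sigma2 / sum(g^2)) else NA_real_
  # behavioural series are serially correlated even after averaging across
  # fish; inflate the iid standard error by the AR(1) equivalent-sample-size
  # factor estimated from the lag-1 residual autocorrelation
  rho <- 0
  if (is.finite(se_k) && n > 10 && sigma2 > 0) {
    r1 <- sum(res[-1] * res[-n]) / sum(res^2)
    rho <- min(max(r1, 0), 0.9)
    se_k <- se_k * sqrt((1 + rho) / (1 - rho))
  }
  zq <- qnorm(1 - (1 - conf_level) / 2 / bonferroni_m)
  k_ci <- k + c(-1, 1) * zq * se_k
  if (unbounded) {
    retention <- Inf
    retention_ci <- c(NA_real_, Inf)
  } else {
    retention <- 1 / k
    se_ret <- se_k / k^2
    retention_ci <- retention + c(-1, 1) * zq * se_ret
    if (is.finite(k_ci[1]) && k_ci[1] <= 0) retention_ci[2] <- Inf
  }
  structure(list(k = k, se_k = se_k, k_ci = k_ci, retention = retention,
                 retention_ci = retention_ci, unbounded = unbounded,
                 t0 = t0, y0 = y0, y_eq = y_eq,
                 conf_level = conf_level, bonferroni_m = bonferroni_m,
                 t = t[sel], y = yi, fitted = fit, residuals = res,
                 sigma = sqrt(sigma2), n = n, resid_ar1 = rho),
            class = "relaxation_fit")
}

#' Retention time of a fitted relaxation
#'
#' @param object a `relaxation_fit`.
#' @return retention time 1/k in seconds (`Inf` when no relaxation was
#'   resolved).
#' @export
retention_time <- function(object) {
  stopifnot(inherits(object, "relaxation_fit"))
  object$retention
}

#' @export
coef.relaxation_fit <- function(object, ...) c(k = object$k)

#' @export
fitted.relaxation_fit <- function(object, ...) object$fitted

#' @export
residuals.relaxation_fit <- function(object, ...) object$residuals

#' Predict the relaxation curve
#'
#' Evaluates the fitted curve; times before `t0` return the equilibrium
#' level `y_eq` (the pre-relaxation mean).
#'
#' @param object a `relaxation_fit`.
#' @param t times in seconds (defaults to the fitting window).
#' @param ... unused.
#' @return predicted mean distance, mm.
#' @export
predict.relaxation_fit <- function(object, t = object$t, ...) {
  ifelse(t < object$t0,
         object$y_eq,
         (object$y0 - object$y_eq) * exp(-object$k * (t - object$t0)) +
           object$y_eq)
}

#' @export
print.relaxation_fit <- function(x, ...) {
  cat("Exponential relaxation fit\n")
  cat(sprintf("  constants: t0 = %g s, y0 = %g mm, y_eq = %g mm\n",
              x$t0, x$y0, x$y_eq))
  if (x$unbounded) {
    cat("  k = 0 (no relaxation resolved); retention time unbounded\n")
  } else {
    cat(sprintf("  k = %.4g 1/s (SE %.3g); retention 1/k = %.3g s\n",
                x$k, x$se_k, x$retention))
  }
  invisible(x)
}

#' @export
summary.relaxation_fit <- function(object, ...) {
  print(object)
  lvl <- 100 * object$conf_level
  bonf <- if (object$bonferroni_m > 1)
    sprintf(" (Bonferroni m = %d)", object$bonferroni_m) else ""
  cat(sprintf("  %g%% CI%s on k: [%.4g, %.4g] 1/s\n", lvl, bonf,
              object$k_ci[1], object$k_ci[2]))
  cat(sprintf("  %g%% CI%s on 1/k: [%.4g, %.4g] s\n", lvl, bonf,
              object$retention_ci[1], object$retention_ci[2]))
  cat(sprintf("  residual SD %.3g mm over %d points\n", object$sigma,
              object$n))
  invisible(object)
}

#' Plot a fitted relaxation curve over the data
#'
#' @param x a `relaxation_fit`.
#' @param ... passed to [plot()].
#' @export
plot.relaxation_fit <- function(x, ...) {
  plot(x$t, x$y, type = "l", col = "grey40",
       xlab = "time (s)", ylab = "mean distance y (mm)", ...)
  lines(x$t, x$fitted, col = "cyan3", lwd = 2)
  abline(h = x$y_eq, lty = 3)
  invisible(x)
}
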