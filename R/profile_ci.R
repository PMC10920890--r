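#' Chi-square ratio threshold for confidence contours
#'
#' FitSpace-style threshold: the boundary of the joint confidence region is
#' `chisq_threshold = chisq_min * (1 + p/(n - p) * F(alpha; p, n - p))`. The
#' reported ratio threshold is `chisq_min / chisq_threshold`, so a scan
#' value is inside the interval while
#' `chisq_min / chisq(theta) >= ratio`.
#'
#' @param n Number of data points.
#' @param p Number of floating parameters.
#' @param alpha Significance level (default 0.05 for 95% limits).
#' @return List with `f_crit`, `inflation` (chisq_threshold / chisq_min)
#'   and `ratio` (its reciprocal).
#' @export
contour_threshold <- function(n, p, alpha = 0.05) {
  stopifnot(n > p, p >= 1)
  f_crit <- stats::qf(1 - alpha, p, n - p)
  inflation <- 1 + p / (n - p) * f_crit
  list(f_crit = f_crit, inflation = inflation, ratio = 1 / inflation)
}

# interpolate the two crossings of chisq(theta) with the threshold; either
# side is open when the scan does not bracket the crossing. Interpolation is
# on the sqrt(delta-chisq) scale, which is locally linear in theta for a
# quadratic profile, so coarse grids do not bias the interval inward.
interval_from_profile <- function(scan, chisq, best_value, chisq_threshold,
                                  chisq_min = min(chisq)) {
  ord <- order(scan)
  scan <- scan[ord]
  chisq <- chisq[ord]
  inside <- chisq <= chisq_threshold
  s_thr <- sqrt(max(chisq_threshold - chisq_min, 0))
  cross <- function(i, j) {
    si <- sqrt(max(chisq[i] - chisq_min, 0))
    sj <- sqrt(max(chisq[j] - chisq_min, 0))
    if (!is.finite(si) || !is.finite(sj) || abs(sj - si) < 1e-300) {
      return((scan[i] + scan[j]) / 2)
    }
    scan[i] + (s_thr - si) * (scan[j] - scan[i]) / (sj - si)
  }
  lower <- NA_real_; upper <- NA_real_
  lower_open <- FALSE; upper_open <- FALSE
  below <- which(scan < best_value & !inside)
  if (length(below)) {
    i <- max(below)
    lower <- cross(i, i + 1L)
  } else lower_open <- TRUE
  above <- which(scan > best_value & !inside)
  if (length(above)) {
    j <- min(above)
    upper <- cross(j - 1L, j)
  } else upper_open <- TRUE
  list(lower = lower, upper = upper,
       lower_open = lower_open, upper_open = upper_open)
}

#' Profile chi-square confidence contour for one rate constant
#'
#' Scans one floating rate over a grid, holding it fixed at each scan value
#' while re-fitting the remaining floating rates, and derives the 95%
#' confidence interval from the F-distribution threshold of
#' [contour_threshold()]. Open-ended bounds (scan does not cross the
#' threshold on one side) are reported as such.
#'
#' @param fit A `kinetic_fit` from [fit_kinetics()].
#' @param parameter Name of the floating rate to scan (e.g. `"k+2"`).
#' @param scan Numeric grid of values for that rate; by default a
#'   log-spaced grid whose range is set by a pilot curvature probe so the
#'   grid resolves the threshold crossings.
#' @param n_scan Grid size for the default scan.
#' @param scan_span Bounds the default scan at `scan_span^4`-fold on each
#'   side (reached when the profile is flat, e.g. open-ended limits).
#' @param alpha Significance level (default 0.05).
#' @return A `confidence_contour`: tibble-bearing list with `profile`
#'   (`value`, `chisq`, `ratio`), `estimate`, `lower`, `upper`,
#'   `lower_open`, `upper_open`, `threshold` (the ratio), `chisq_min`.
#' @export
confidence_contour <- function(fit, parameter, scan = NULL, n_scan = 13L,
                               scan_span = 4, alpha = 0.05) {
  stopifnot(inherits(fit, "kinetic_fit"))
  fl <- floating_rates(fit$scheme)
  if (!parameter %in% fl) stop("'", parameter, "' is not a floating rate")
  est <- fit$estimates[[parameter]]
  others <- setdiff(fl, parameter)
  data <- fit$data
  design <- fit$design
  w <- if (is.null(fit$sigma)) rep(1, nrow(data)) else 1 / fit$sigma
  key <- paste(data$substrate_uM, data$time_min)
  chisq_at <- function(value) {
    resid_fun <- function(theta) {
      floats <- stats::setNames(c(exp(theta), value), c(others, parameter))
      m <- tryCatch(model_observable(fit$scheme, floats, design),
                    error = function(e) NULL)
      if (is.null(m)) return(rep(1e6, nrow(data)))
      mk <- stats::setNames(m$model, paste(m$substrate_uM, m$time_min))
      (data$product_uM - mk[key]) * w
    }
    if (!length(others)) return(sum(resid_fun(numeric(0))^2))
    start <- log(fit$estimates[others])
    refit <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 100, epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(refit)) Inf else sum(refit$fvec^2)
  }
  thr <- contour_threshold(fit$n_obs, fit$n_par, alpha)
  chisq_threshold <- fit$chisq_min * thr$inflation
  if (is.null(scan)) {
    # pilot curvature probe sets the scan range so the grid resolves the
    # crossing instead of wasting points far outside the interval
    delta_thr <- max(chisq_threshold - fit$chisq_min, 1e-12)
    max_log <- log(scan_span^4)
    side_span <- function(factor) {
      d <- chisq_at(est * factor) - fit$chisq_min
      if (!is.finite(d) || d <= delta_thr * 1e-6) return(max_log)
      min(max_log, 2.5 * abs(log(factor)) * sqrt(delta_thr / d))
    }
    lo <- side_span(1 / 1.05)
    hi <- side_span(1.05)
    scan <- exp(log(est) + seq(-lo, hi, length.out = n_scan))
  }
  chisq <- vapply(scan, chisq_at, numeric(1))
  ci <- interval_from_profile(scan, chisq, est, chisq_threshold,
                              chisq_min = fit$chisq_min)
  structure(
    list(parameter = parameter, estimate = est,
         profile = tibble::tibble(value = scan, chisq = chisq,
                                  ratio = fit$chisq_min / chisq),
         lower = ci$lower, upper = ci$upper,
         lower_open = ci$lower_open, upper_open = ci$upper_open,
         threshold = thr$ratio, chisq_min = fit$chisq_min,
         alpha = alpha),
    class = "confidence_contour")
}

#' @export
print.confidence_contour <- function(x, ...) {
  fmt <- function(v, open, side) {
    if (open) paste0("open (", side, " limit not bracketed)") else format(v, digits = 4)
  }
  cat("<confidence_contour> ", x$parameter, " = ", format(x$estimate, digits = 4),
      "\n  ", 100 * (1 - x$alpha), "% CI: [",
      fmt(x$lower, x$lower_open, "lower"), ", ",
      fmt(x$upper, x$upper_open, "upper"), "]  (chisq ratio threshold ",
      format(x$threshold, digits = 3), ")\n", sep = "")
  invisible(x)
}
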