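#' Fit the Hill dose-response equation
#'
#' `y = d + (a - d) * x^b / (c^b + x^b)` with `y` the output signal, `x` the
#' ligand concentration, `d` the background signal, `a` the maximum signal,
#' `b` the Hill coefficient and `c` the EC50. Nonlinear least squares with
#' data-driven initialization (`d = min(y)`, `a = max(y)`, `c` at the
#' geometric middle of the positive `x`, `b = 1`). `x = 0` is handled by the
#' equation directly (`y = d`).
#'
#' @param x Ligand concentrations (same units as the returned EC50).
#' @param y Signals.
#' @return A `hill_fit`: list with `a`, `d`, `b`, `c` (EC50), `ec50`,
#'   `ec50_se` (delta-method standard error from the fit covariance),
#'   `covariance`, `residual_sd`, `degenerate`, `spanning` (whether the data
#'   bracket the inflection), `fit` (the nls object) and `data`.
#' @export
fit_hill <- function(x, y) {
  stopifnot(length(x) == length(y), all(x >= 0))
  if (length(x) < 5) warning("fewer than 5 points; Hill fit may be unreliable")
  if (stats::sd(y) == 0) {
    out <- list(a = NA_real_, d = y[1], b = NA_real_, c = NA_real_,
                ec50 = NA_real_, ec50_se = NA_real_, covariance = NULL,
                residual_sd = 0, degenerate = TRUE, spanning = FALSE,
                fit = NULL, data = tibble::tibble(x = x, y = y))
    warning("constant signal: Hill fit degenerate, no EC50 reported")
    return(structure(out, class = "hill_fit"))
  }
  xp <- x[x > 0]
  start <- list(a = max(y), d = min(y),
                c = exp(mean(log(range(xp)))), b = 1)
  fit <- minpack.lm::nlsLM(
    y ~ d + (a - d) * ifelse(x > 0, x^b / (c^b + x^b), 0),
    data = data.frame(x = x, y = y), start = start,
    lower = c(a = -Inf, d = -Inf, c = 1e-12, b = 1e-6),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  mid <- cf[["c"]]
  spanning <- any(x < mid) && any(x > mid)
  if (!spanning) warning("data do not span the fitted EC50; fit flagged unreliable")
  structure(
    list(a = cf[["a"]], d = cf[["d"]], b = cf[["b"]], c = cf[["c"]],
         ec50 = cf[["c"]],
         ec50_se = if (!is.null(vc)) sqrt(vc["c", "c"]) else NA_real_,
         covariance = vc, residual_sd = stats::sigma(fit),
         degenerate = FALSE, spanning = spanning, fit = fit,
         data = tibble::tibble(x = x, y = y)),
    class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<hill_fit> degenerate (constant signal); no EC50\n")
    return(invisible(x))
  }
  cat(sprintf("<hill_fit> EC50 = %.4g (SE %.3g), Hill b = %.3g, a = %.4g, d = %.4g%s\n",
              x$ec50, x$ec50_se, x$b, x$a, x$d,
              if (!x$spanning) "  [non-spanning data]" else ""))
  invisible(x)
}

#' Predict from a Hill fit
#' @param object A `hill_fit`.
#' @param newdata Optional numeric vector of concentrations.
#' @param ... Unused.
#' @return Predicted signals.
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else newdata
  with(object, d + (a - d) * ifelse(x > 0, x^b / (c^b + x^b), 0))
}

#' Fit a Boltzmann sigmoid to a thermal melt curve
#'
#' `F(T) = F_min + (F_max - F_min) / (1 + exp((Tm - T) / slope))`; Tm is the
#' inflection temperature. Works identically for ascending or descending
#' temperature series. A biphasic curve (two well-separated candidate
#' transitions in the smoothed derivative) is flagged and the fit is
#' restricted to the first transition with a warning.
#'
#' @param temperature Temperatures in deg C.
#' @param fluorescence Fluorescence signal.
#' @return A `melt_fit`: list with `f_min`, `f_max`, `tm`, `slope`,
#'   `tm_se`, `biphasic`, `fit`, `data`.
#' @export
fit_boltzmann_melt <- function(temperature, fluorescence) {
  stopifnot(length(temperature) == length(fluorescence),
            length(temperature) >= 5)
  ord <- order(temperature)
  Tv <- temperature[ord]
  Fv <- fluorescence[ord]
  # crude transition scan on the first-difference curve
  dF <- diff(Fv) / diff(Tv)
  k <- max(1L, min(5L, length(dF)))
  sm <- stats::filter(dF, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- 0
  peak <- which.max(abs(sm))
  is_peak <- abs(sm) > 0.5 * abs(sm[peak])
  runs <- rle(as.vector(is_peak))
  n_trans <- sum(runs$values)
  biphasic <- n_trans >= 2
  if (biphasic) {
    warning("melt curve appears biphasic; fitting the first transition only")
    first_end <- cumsum(runs$lengths)[which(runs$values)[1]]
    cutoff <- min(length(Tv), first_end + max(3L, k))
    keep <- seq_len(cutoff)
    Tv <- Tv[keep]; Fv <- Fv[keep]
  }
  start <- list(f_min = min(Fv), f_max = max(Fv),
                tm = Tv[which.min(abs(Fv - (min(Fv) + max(Fv)) / 2))],
                slope = diff(range(Tv)) / 20)
  fit <- minpack.lm::nlsLM(
    Fv ~ f_min + (f_max - f_min) / (1 + exp((tm - Tv) / slope)),
    data = data.frame(Tv = Tv, Fv = Fv), start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(
    list(f_min = cf[["f_min"]], f_max = cf[["f_max"]], tm = cf[["tm"]],
         slope = cf[["slope"]],
         tm_se = if (!is.null(vc)) sqrt(vc["tm", "tm"]) else NA_real_,
         biphasic = biphasic, fit = fit,
         data = tibble::tibble(temperature = temperature,
                               fluorescence = fluorescence)),
    class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> Tm = %.2f degC (SE %.3g), slope = %.3g degC%s\n",
              x$tm, x$tm_se, x$slope,
              if (x$biphasic) "  [biphasic curve, first transition]" else ""))
  invisible(x)
}

#' Predict from a Boltzmann melt fit
#' @param object A `melt_fit`.
#' @param newdata Optional numeric vector of temperatures.
#' @param ... Unused.
#' @return Predicted fluorescence.
#' @export
predict.melt_fit <- function(object, newdata = NULL, ...) {
  Tv <- if (is.null(newdata)) object$data$temperature else newdata
  with(object, f_min + (f_max - f_min) / (1 + exp((tm - Tv) / slope)))
}
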