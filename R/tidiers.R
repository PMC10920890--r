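#' Tidy a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return Tibble with one row per floating rate: `term`, `estimate`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimates), estimate = unname(x$estimates))
}

#' @rdname tidy.kinetic_fit
#' @return For `glance()`: one-row tibble with `chisq_min`, `n_obs`,
#'   `n_par`, and the derived `kcat`, `kcat_over_km`, `km` when available.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble::tibble(chisq_min = x$chisq_min, n_obs = x$n_obs, n_par = x$n_par,
                 kcat = x$kcat %||% NA_real_,
                 kcat_over_km = x$kcat_over_km %||% NA_real_,
                 km = x$km %||% NA_real_)
}

#' Tidy a confidence contour
#'
#' @param x A `confidence_contour`.
#' @param ... Unused.
#' @return The profile tibble (`value`, `chisq`, `ratio`).
#' @export
tidy.confidence_contour <- function(x, ...) x$profile

#' @rdname tidy.confidence_contour
#' @export
glance.confidence_contour <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, estimate = x$estimate,
                 lower = x$lower, upper = x$upper,
                 lower_open = x$lower_open, upper_open = x$upper_open,
                 threshold = x$threshold, chisq_min = x$chisq_min)
}

#' Tidy a Hill fit
#'
#' @param x A `hill_fit`.
#' @param ... Unused.
#' @return Tibble with `term` (`a`, `d`, `b`, `c`) and `estimate`.
#' @export
tidy.hill_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "d", "b", "c"),
                 estimate = c(x$a, x$d, x$b, x$c))
}

#' @rdname tidy.hill_fit
#' @export
glance.hill_fit <- function(x, ...) {
  tibble::tibble(ec50 = x$ec50, ec50_se = x$ec50_se, hill = x$b,
                 residual_sd = x$residual_sd, degenerate = x$degenerate,
                 spanning = x$spanning)
}

#' Tidy a Boltzmann melt fit
#'
#' @param x A `melt_fit`.
#' @param ... Unused.
#' @return Tibble with `term` (`f_min`, `f_max`, `tm`, `slope`) and
#'   `estimate`.
#' @export
tidy.melt_fit <- function(x, ...) {
  tibble::tibble(term = c("f_min", "f_max", "tm", "slope"),
                 estimate = c(x$f_min, x$f_max, x$tm, x$slope))
}

#' @rdname tidy.melt_fit
#' @export
glance.melt_fit <- function(x, ...) {
  tibble::tibble(tm = x$tm, tm_se = x$tm_se, slope = x$slope,
                 biphasic = x$biphasic)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return The per-stratum accuracy tibble.
#' @export
tidy.eval_report <- function(x, ...) x$strata

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy, n = x$n)
}
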