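#' Build a mass-action kinetic scheme
#'
#' A scheme is a list of reversible steps, each with a forward and reverse
#' rate constant, plus parameter roles: `fixed` (locked value), `float`
#' (estimated, with an initial value) or `linked` (always equal to another
#' rate). Units are uM and min throughout.
#'
#' @param reactions List of steps; each is
#'   `list(reactants =, products =, kf =, kr =)` with species name vectors
#'   and rate-constant names.
#' @param roles Named list keyed by rate-constant name; each element is
#'   `list(role = "fixed", value =)`, `list(role = "float", init =)` or
#'   `list(role = "linked", to =)`.
#' @param observable Character vector of species summed to form the
#'   observed signal.
#' @param name Scheme label.
#' @return A list of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(reactions, roles, observable, name = "scheme") {
  species <- unique(unlist(lapply(reactions, function(r) c(r$reactants, r$products))))
  for (r in reactions) stopifnot(!is.null(r$kf), !is.null(r$kr))
  rate_names <- unlist(lapply(reactions, function(r) c(r$kf, r$kr)))
  missing_roles <- setdiff(rate_names, names(roles))
  if (length(missing_roles)) stop("no role for rate(s): ",
                                  paste(missing_roles, collapse = ", "))
  structure(list(reactions = reactions, roles = roles, species = species,
                 observable = observable, name = name),
            class = "kinetic_scheme")
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("<kinetic_scheme> ", x$name, ": ", length(x$reactions), " steps, ",
      length(x$species), " species; observable = ",
      paste(x$observable, collapse = " + "), "\n", sep = "")
  cat("  floating:", paste(floating_rates(x), collapse = ", "), "\n")
  invisible(x)
}

#' Names of the floating rate constants of a scheme
#' @param scheme A `kinetic_scheme`.
#' @return Character vector.
#' @export
floating_rates <- function(scheme) {
  names(scheme$roles)[vapply(scheme$roles, function(r) r$role == "float", logical(1))]
}

# assemble the full named rate vector from floating values + roles
assemble_rates <- function(scheme, floats) {
  k <- vapply(scheme$roles, function(r) {
    switch(r$role, fixed = r$value, float = NA_real_, linked = NA_real_)
  }, numeric(1))
  k[names(floats)] <- floats
  for (nm in names(scheme$roles)) {
    if (scheme$roles[[nm]]$role == "linked") k[nm] <- k[[scheme$roles[[nm]]$to]]
  }
  if (anyNA(k)) stop("unresolved rate value(s): ",
                     paste(names(k)[is.na(k)], collapse = ", "))
  k
}

#' The minimal irreversible turnover scheme
#'
#' Steps: E + S = ES, ES = EP, EP = E + P, S = P2 (background substrate
#' oxidation). Reverse rates of steps 1-3 are locked at 0 (irreversible);
#' the product-release rate is locked at 10000 min^-1 so it does not limit
#' turnover; the oxidation rate defaults to 0.00547 min^-1. The floating
#' rates are `k+1` (= kcat/Km, uM^-1 min^-1) and `k+2` (= kcat, min^-1);
#' observable is EP + P.
#'
#' @param k_oxidation Background substrate oxidation rate, min^-1.
#' @param k_release Product release rate, min^-1.
#' @param init Named initial values for the floating rates.
#' @return A `kinetic_scheme`.
#' @export
build_minimal_scheme <- function(k_oxidation = 0.00547, k_release = 10000,
                                 init = c(`k+1` = 0.1, `k+2` = 10)) {
  kinetic_scheme(
    reactions = list(
      list(reactants = c("E", "S"), products = "ES", kf = "k+1", kr = "k-1"),
      list(reactants = "ES", products = "EP", kf = "k+2", kr = "k-2"),
      list(reactants = "EP", products = c("E", "P"), kf = "k+3", kr = "k-3"),
      list(reactants = "S", products = "P2", kf = "k+4", kr = "k-4")
    ),
    roles = list(
      `k+1` = list(role = "float", init = unname(init["k+1"])),
      `k-1` = list(role = "fixed", value = 0),
      `k+2` = list(role = "float", init = unname(init["k+2"])),
      `k-2` = list(role = "fixed", value = 0),
      `k+3` = list(role = "fixed", value = k_release),
      `k-3` = list(role = "fixed", value = 0),
      `k+4` = list(role = "fixed", value = k_oxidation),
      `k-4` = list(role = "fixed", value = 0)
    ),
    observable = c("EP", "P"), name = "minimal"
  )
}

#' The substrate-inhibition scheme
#'
#' Extends the minimal scheme with nonproductive complexes: E + S = SE,
#' SE + S = SES, ES + S = SES, and background oxidation S = P2. The
#' inhibition on-rates `k+4` and `k+6` are locked at 100 uM^-1 min^-1; the
#' off-rates `k-4` and `k-6` float as linked parameters (their common value
#' sets the inhibition constant); `k+5` is linked to `k+1`. Floating rates:
#' `k+1`, `k+2`, `k-4`.
#'
#' @inheritParams build_minimal_scheme
#' @param k_inhib_on Locked inhibition on-rate, uM^-1 min^-1.
#' @return A `kinetic_scheme`.
#' @export
build_substrate_inhibition_scheme <- function(k_oxidation = 0.00547,
                                              k_release = 10000,
                                              k_inhib_on = 100,
                                              init = c(`k+1` = 0.1, `k+2` = 10,
                                                       `k-4` = 1000)) {
  kinetic_scheme(
    reactions = list(
      list(reactants = c("E", "S"), products = "ES", kf = "k+1", kr = "k-1"),
      list(reactants = "ES", products = "EP", kf = "k+2", kr = "k-2"),
      list(reactants = "EP", products = c("E", "P"), kf = "k+3", kr = "k-3"),
      list(reactants = c("E", "S"), products = "SE", kf = "k+4", kr = "k-4"),
      list(reactants = c("SE", "S"), products = "SES", kf = "k+5", kr = "k-5"),
      list(reactants = c("ES", "S"), products = "SES", kf = "k+6", kr = "k-6"),
      list(reactants = "S", products = "P2", kf = "k+7", kr = "k-7")
    ),
    roles = list(
      `k+1` = list(role = "float", init = unname(init["k+1"])),
      `k-1` = list(role = "fixed", value = 0),
      `k+2` = list(role = "float", init = unname(init["k+2"])),
      `k-2` = list(role = "fixed", value = 0),
      `k+3` = list(role = "fixed", value = k_release),
      `k-3` = list(role = "fixed", value = 0),
      `k+4` = list(role = "fixed", value = k_inhib_on),
      `k-4` = list(role = "float", init = unname(init["k-4"])),
      `k+5` = list(role = "linked", to = "k+1"),
      `k-5` = list(role = "fixed", value = 0),
      `k+6` = list(role = "fixed", value = k_inhib_on),
      `k-6` = list(role = "linked", to = "k-4"),
      `k+7` = list(role = "fixed", value = k_oxidation),
      `k-7` = list(role = "fixed", value = 0)
    ),
    observable = c("EP", "P"), name = "substrate_inhibition"
  )
}

# stoichiometry of the directed reactions (forward then reverse per step)
directed_reactions <- function(scheme) {
  out <- list()
  for (r in scheme$reactions) {
    out[[length(out) + 1L]] <- list(from = r$reactants, to = r$products, k = r$kf)
    out[[length(out) + 1L]] <- list(from = r$products, to = r$reactants, k = r$kr)
  }
  out
}

#' Simulate a kinetic scheme
#'
#' Stiff mass-action ODE integration (deSolve lsoda, rtol 1e-8, atol 1e-12
#' uM) of the scheme at given rate values and initial concentrations.
#'
#' @param scheme A `kinetic_scheme`.
#' @param rates Named vector of values for the floating rates (fixed and
#'   linked rates are filled in from the scheme roles), or a full named rate
#'   vector.
#' @param init Named initial concentrations in uM; unnamed species start at
#'   0.
#' @param times Numeric vector of times in min (0 is prepended
#'   automatically for the integrator).
#' @return Tibble with `time` plus one column per species and `observable`
#'   (the scheme's observable sum), at the requested times.
#' @export
simulate_scheme <- function(scheme, rates, init, times) {
  stopifnot(all(init >= 0), all(diff(sort(times)) > 0))
  k <- assemble_rates(scheme, rates)
  dr <- directed_reactions(scheme)
  n_sp <- length(scheme$species)
  # keep directed reactions with nonzero rate; mass action has <= 2 reactants
  active <- dr[vapply(dr, function(r) k[[r$k]] > 0, logical(1))]
  if (!length(active)) {
    out <- tibble::as_tibble(c(list(time = times),
                               stats::setNames(as.list(rep(0, n_sp)), scheme$species)))
    for (sp in names(init)) out[[sp]] <- init[[sp]]
    out$observable <- rowSums(out[, scheme$observable, drop = FALSE])
    return(out)
  }
  kv <- vapply(active, function(r) k[[r$k]], numeric(1))
  r1 <- vapply(active, function(r) match(r$from[1], scheme$species), integer(1))
  r2 <- vapply(active, function(r) {
    if (length(r$from) > 1) match(r$from[2], scheme$species) else NA_integer_
  }, integer(1))
  if (any(vapply(active, function(r) length(r$from) > 2, logical(1)))) {
    stop("mass-action steps with more than two reactants are not supported")
  }
  S <- matrix(0, n_sp, length(active))
  for (j in seq_along(active)) {
    for (sp in active[[j]]$from) {
      i <- match(sp, scheme$species); S[i, j] <- S[i, j] - 1
    }
    for (sp in active[[j]]$to) {
      i <- match(sp, scheme$species); S[i, j] <- S[i, j] + 1
    }
  }
  uni <- is.na(r2)
  r2x <- ifelse(uni, 1L, r2)
  rhs <- function(t, y, parms) {
    f2 <- y[r2x]
    f2[uni] <- 1
    list(as.vector(S %*% (kv * y[r1] * f2)))
  }
  jac <- function(t, y, parms) {
    dR <- matrix(0, length(active), n_sp)
    for (j in seq_along(active)) {
      if (uni[j]) {
        dR[j, r1[j]] <- kv[j]
      } else if (r1[j] == r2[j]) {
        dR[j, r1[j]] <- 2 * kv[j] * y[r1[j]]
      } else {
        dR[j, r1[j]] <- kv[j] * y[r2[j]]
        dR[j, r2[j]] <- kv[j] * y[r1[j]]
      }
    }
    S %*% dR
  }
  y0 <- stats::setNames(numeric(n_sp), scheme$species)
  y0[names(init)] <- init
  tt <- sort(unique(c(0, times)))
  sol <- suppressWarnings(
    deSolve::lsoda(y0, tt, rhs, parms = NULL, jacfunc = jac,
                   jactype = "fullusr", rtol = 1e-8, atol = 1e-12,
                   maxsteps = 100000))
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(tt)) {
    stop("ODE integration failed for scheme '", scheme$name,
         "' (possible stiffness; lsoda istate ", attr(sol, "istate")[1], ")")
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  out <- out[match(times, out$time), , drop = FALSE]
  out$observable <- rowSums(out[, scheme$observable, drop = FALSE])
  out
}

#' The paper-style progress-curve assay design
#'
#' 3.5 nM (0.0035 uM) enzyme; substrate at 15.625, 31.25, 62.5, 125, 250
#' and 500 uM; hourly sampling over 4 h; triplicate.
#'
#' @param enzyme_uM Enzyme concentration, uM.
#' @param substrate_uM Substrate levels, uM.
#' @param times_min Sampling times, min.
#' @param replicates Number of replicates.
#' @return A list of class `assay_design`.
#' @export
assay_design <- function(enzyme_uM = 0.0035,
                         substrate_uM = c(15.625, 31.25, 62.5, 125, 250, 500),
                         times_min = c(60, 120, 180, 240), replicates = 3L) {
  stopifnot(enzyme_uM >= 0, all(substrate_uM >= 0), all(diff(times_min) > 0))
  structure(list(enzyme_uM = enzyme_uM, substrate_uM = substrate_uM,
                 times_min = times_min, replicates = as.integer(replicates)),
            class = "assay_design")
}

# model observable for every (substrate, time) pair of a design
model_observable <- function(scheme, floats, design) {
  rows <- list()
  for (s0 in design$substrate_uM) {
    sim <- simulate_scheme(scheme, floats,
                           init = c(E = design$enzyme_uM, S = s0),
                           times = design$times_min)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      substrate_uM = s0, time_min = design$times_min, model = sim$observable)
  }
  dplyr::bind_rows(rows)
}

#' Globally fit a kinetic scheme to progress curves
#'
#' Least squares over all substrate levels, times and replicates
#' simultaneously (unit weights unless `sigma` is given), honoring the
#' scheme's fixed/linked roles. Floating rates are optimized on the log
#' scale by Levenberg-Marquardt with multi-start from log-spaced initial
#' values.
#'
#' @param scheme A `kinetic_scheme`.
#' @param data Tibble with columns `substrate_uM`, `time_min`,
#'   `product_uM` and optionally `replicate`.
#' @param design An [assay_design()]; its enzyme concentration and
#'   substrate levels must cover the data (defaults to levels found in the
#'   data with the paper-style enzyme concentration).
#' @param sigma Optional per-point standard deviations for weighting.
#' @param n_start Number of multi-start scale factors (log-spaced around
#'   the role initial values).
#' @return A `kinetic_fit`: list with `estimates` (named vector),
#'   `chisq_min`, `n_obs`, `n_par`, `scheme`, `design`, `data`, and derived
#'   `kcat`, `kcat_over_km`, `km` when `k+1`/`k+2` float.
#' @export
fit_kinetics <- function(scheme, data, design = NULL, sigma = NULL,
                         n_start = 3L) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("substrate_uM", "time_min", "product_uM") %in% names(data)))
  if (is.null(design)) {
    design <- assay_design(substrate_uM = sort(unique(data$substrate_uM)),
                           times_min = sort(unique(data$time_min)))
  }
  fl <- floating_rates(scheme)
  if (nrow(data) < length(fl)) stop("fewer observations than floating parameters")
  w <- if (is.null(sigma)) rep(1, nrow(data)) else 1 / sigma
  key <- paste(data$substrate_uM, data$time_min)
  resid_fun <- function(theta) {
    floats <- stats::setNames(exp(theta), fl)
    # integrator failure at an extreme trial point -> large residuals so
    # the optimizer retreats instead of aborting the fit
    m <- tryCatch(model_observable(scheme, floats, design),
                  error = function(e) NULL)
    if (is.null(m)) return(rep(1e6, nrow(data)))
    mk <- stats::setNames(m$model, paste(m$substrate_uM, m$time_min))
    (data$product_uM - mk[key]) * w
  }
  init0 <- log(vapply(fl, function(nm) scheme$roles[[nm]]$init, numeric(1)))
  scales <- if (n_start <= 1) 0 else seq(-1, 1, length.out = n_start)
  best <- NULL
  for (sc in scales) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = init0 + sc * log(10), fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200, epsfcn = 1e-6)),
      error = function(e) NULL)
    if (is.null(fit)) next
    chisq <- sum(fit$fvec^2)
    if (is.null(best) || chisq < best$chisq) {
      best <- list(par = fit$par, chisq = chisq, info = fit$info)
    }
  }
  if (is.null(best)) stop("kinetic fit failed to converge from any start")
  est <- stats::setNames(exp(best$par), fl)
  out <- structure(
    list(estimates = est, chisq_min = best$chisq, n_obs = nrow(data),
         n_par = length(fl), scheme = scheme, design = design, data = data,
         sigma = sigma),
    class = "kinetic_fit")
  if (all(c("k+1", "k+2") %in% fl)) {
    out$kcat <- unname(est["k+2"])
    out$kcat_over_km <- unname(est["k+1"])
    out$km <- out$kcat / out$kcat_over_km
  }
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> scheme '", x$scheme$name, "': chisq_min = ",
      format(x$chisq_min, digits = 6), " over ", x$n_obs, " points\n", sep = "")
  for (nm in names(x$estimates)) {
    cat(sprintf("  %-5s = %.6g\n", nm, x$estimates[[nm]]))
  }
  if (!is.null(x$km)) {
    cat(sprintf("  kcat = %.4g min^-1, kcat/Km = %.4g uM^-1 min^-1, Km = %.4g uM\n",
                x$kcat, x$kcat_over_km, x$km))
  }
  invisible(x)
}

#' Derive Km from kcat and kcat/Km
#'
#' The Michaelis constant as the ratio of the turnover number to the
#' catalytic efficiency.
#'
#' @param kcat Turnover number, min^-1.
#' @param kcat_over_km Catalytic efficiency, uM^-1 min^-1.
#' @return Km in uM.
#' @export
#' @examples
#' derive_km(73, 1.18)  # ~62 uM
derive_km <- function(kcat, kcat_over_km) {
  kcat / kcat_over_km
}
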