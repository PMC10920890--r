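test_that("the minimal scheme has the published structure and defaults", {
  sc <- build_minimal_scheme()
  expect_setequal(sc$species, c("E", "S", "ES", "EP", "P", "P2"))
  expect_equal(length(sc$reactions), 4)
  expect_equal(sc$roles[["k+4"]]$value, 0.00547)     # substrate oxidation
  expect_equal(sc$roles[["k+3"]]$value, 10000)       # non-limiting release
  expect_setequal(floating_rates(sc), c("k+1", "k+2"))
  expect_equal(sc$observable, c("EP", "P"))
  for (nm in c("k-1", "k-2", "k-3")) {
    expect_equal(sc$roles[[nm]]$value, 0)
  }
})

test_that("the substrate-inhibition scheme links its inhibition rates", {
  sc <- build_substrate_inhibition_scheme()
  expect_setequal(sc$species, c("E", "S", "ES", "EP", "P", "SE", "SES", "P2"))
  expect_setequal(floating_rates(sc), c("k+1", "k+2", "k-4"))
  expect_equal(sc$roles[["k+4"]]$value, 100)
  expect_equal(sc$roles[["k+6"]]$value, 100)
  k <- voxdesign:::assemble_rates(sc, c(`k+1` = 2, `k+2` = 50, `k-4` = 777))
  expect_equal(k[["k-6"]], 777)   # linked to k-4
  expect_equal(k[["k+5"]], 2)     # linked to k+1
  expect_equal(k[["k+7"]], 0.00547)
})

test_that("simulated trajectories satisfy closed-form limits", {
  sc <- build_minimal_scheme()
  fl <- c(`k+1` = 1.18, `k+2` = 73)
  E <- 0.0035
  km <- derive_km(73, 1.18)
  # no enzyme, no oxidation: substrate constant, observable zero
  sc0 <- build_minimal_scheme(k_oxidation = 0)
  sim0 <- simulate_scheme(sc0, fl, init = c(E = 0, S = 100), times = c(60, 240))
  expect_equal(sim0$S, c(100, 100), tolerance = 1e-10)
  expect_equal(sim0$observable, c(0, 0))
  # S = Km: initial observable slope = kcat * E / 2 within 2%
  sim1 <- simulate_scheme(sc, fl, init = c(E = E, S = km), times = 0.5)
  expect_equal(sim1$observable / 0.5, 73 * E / 2, tolerance = 0.02)
  # S << Km: first-order limit, slope = (kcat/Km) * E * S within 1%
  s_lo <- km / 120
  sim2 <- simulate_scheme(sc, fl, init = c(E = E, S = s_lo), times = 0.2)
  expect_equal(sim2$observable / 0.2, 1.18 * E * s_lo, tolerance = 0.01)
})

test_that("mass is conserved along trajectories", {
  sc <- build_substrate_inhibition_scheme()
  fl <- c(`k+1` = 1.18, `k+2` = 73, `k-4` = 5000)
  sim <- simulate_scheme(sc, fl, init = c(E = 0.0035, S = 500),
                         times = seq(30, 240, by = 30))
  e_tot <- sim$E + sim$ES + sim$EP + sim$SE + sim$SES
  expect_lt(max(abs(e_tot - 0.0035)) / 0.0035, 1e-6)
  s_tot <- sim$S + sim$ES + sim$EP + sim$P + sim$P2 +
    sim$SE + 2 * sim$SES
  expect_lt(max(abs(s_tot - 500)) / 500, 1e-6)
})

test_that("zeroed inhibition reproduces the minimal scheme exactly", {
  fl2 <- c(`k+1` = 1.18, `k+2` = 73)
  base <- simulate_scheme(build_minimal_scheme(), fl2,
                          init = c(E = 0.0035, S = 250),
                          times = c(60, 120, 240))
  no_inhib <- simulate_scheme(
    build_substrate_inhibition_scheme(k_inhib_on = 0),
    c(fl2, `k-4` = 1), init = c(E = 0.0035, S = 250),
    times = c(60, 120, 240))
  expect_equal(no_inhib$observable, base$observable, tolerance = 1e-8)
  # and with very weak binding (k-4 -> large) trajectories converge too
  weak <- simulate_scheme(build_substrate_inhibition_scheme(),
                          c(fl2, `k-4` = 1e8),
                          init = c(E = 0.0035, S = 250),
                          times = c(60, 120, 240))
  expect_equal(weak$observable, base$observable, tolerance = 1e-3)
})

test_that("noiseless global fits recover the generating rates", {
  sc <- build_minimal_scheme()
  truth <- c(`k+1` = 1.18, `k+2` = 73)
  d <- make_kinetics_curves(sc, truth, design = small_design(),
                            noise_frac = 0, seed = 1)
  fit <- fit_kinetics(sc, d, design = small_design(), n_start = 1)
  expect_lt(max(abs(fit$estimates - truth) / truth), 0.001)
  expect_equal(fit$km, derive_km(73, 1.18), tolerance = 0.01)
})

test_that("Km derives from kcat over catalytic efficiency", {
  expect_equal(round(derive_km(73, 1.18)), 62)
  expect_equal(derive_km(10, 0.5), 20)
})

test_that("fits are invariant to row order and to time rescaling", {
  sc <- build_minimal_scheme()
  truth <- c(`k+1` = 1.18, `k+2` = 73)
  d <- make_kinetics_curves(sc, truth, design = small_design(),
                            noise_frac = 0.02, seed = 5)
  f1 <- fit_kinetics(sc, d, design = small_design(), n_start = 1)
  set.seed(7)
  f2 <- fit_kinetics(sc, d[sample(nrow(d)), ], design = small_design(),
                     n_start = 1)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
  expect_equal(f1$chisq_min, f2$chisq_min, tolerance = 1e-8)
  # time in hours with rates per hour: estimates scale reciprocally
  d_h <- d
  d_h$time_min <- d$time_min / 60
  sc_h <- build_minimal_scheme(k_oxidation = 0.00547 * 60,
                               k_release = 10000 * 60)
  design_h <- assay_design(substrate_uM = small_design()$substrate_uM,
                           times_min = small_design()$times_min / 60,
                           replicates = 1L)
  f_h <- fit_kinetics(sc_h, d_h, design = design_h, n_start = 1)
  expect_equal(f_h$estimates / 60, f1$estimates, tolerance = 1e-3)
})

test_that("the contour ratio peaks at 1 at the best fit", {
  sc <- build_minimal_scheme()
  truth <- c(`k+1` = 1.18, `k+2` = 73)
  d <- make_kinetics_curves(sc, truth, design = small_design(),
                            noise_frac = 0.02, seed = 9)
  fit <- fit_kinetics(sc, d, design = small_design(), n_start = 1)
  cc <- confidence_contour(fit, "k+2",
                           scan = fit$estimates[["k+2"]] * c(0.9, 1, 1.1))
  expect_equal(max(cc$profile$ratio), 1, tolerance = 1e-3)
  expect_equal(which.max(cc$profile$ratio), 2L)
  expect_true(cc$lower <= fit$estimates[["k+2"]])
  expect_true(cc$upper >= fit$estimates[["k+2"]])
})

test_that("profile contours reproduce the analytic linear-model interval", {
  # one-parameter linear fixture: y = b x + noise, intercept known at 0.
  # The F-threshold profile interval then equals the exact t interval.
  set.seed(12)
  x <- seq(1, 10, length.out = 20)
  b_true <- 2.5
  y <- b_true * x + rnorm(20, sd = 0.8)
  b_hat <- sum(x * y) / sum(x^2)
  rss <- function(b) sum((y - b * x)^2)
  chisq_min <- rss(b_hat)
  n <- 20; p <- 1
  thr <- contour_threshold(n, p)
  expect_equal(thr$ratio, 1 / (1 + p / (n - p) * qf(0.95, p, n - p)))
  # analytic interval: b_hat +/- t * s / sqrt(Sxx)
  s2 <- chisq_min / (n - p)
  half_t <- qt(0.975, n - p) * sqrt(s2 / sum(x^2))
  scan <- seq(b_hat - 3 * half_t, b_hat + 3 * half_t, length.out = 41)
  ci <- voxdesign:::interval_from_profile(
    scan, vapply(scan, rss, numeric(1)), b_hat,
    chisq_min * thr$inflation, chisq_min = chisq_min)
  expect_equal(ci$lower, b_hat - half_t, tolerance = 0.05 * half_t)
  expect_equal(ci$upper, b_hat + half_t, tolerance = 0.05 * half_t)
})

test_that("open-ended contour sides are flagged rather than invented", {
  set.seed(3)
  x <- seq(1, 10, length.out = 12)
  y <- 2 * x + rnorm(12, sd = 0.5)
  b_hat <- sum(x * y) / sum(x^2)
  rss <- function(b) sum((y - b * x)^2)
  chisq_min <- rss(b_hat)
  thr <- contour_threshold(12, 1)
  # scan only above the estimate: lower side cannot be bracketed
  scan <- seq(b_hat, b_hat + 1, length.out = 11)
  ci <- voxdesign:::interval_from_profile(
    scan, vapply(scan, rss, numeric(1)), b_hat,
    chisq_min * thr$inflation, chisq_min = chisq_min)
  expect_true(ci$lower_open)
  expect_false(ci$upper_open)
})
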