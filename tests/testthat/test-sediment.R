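test_that("porosity follows the water-loss arithmetic of a core slice", {
  expect_equal(round(porosity(100, 100 - 29.04), 3), 0.5)
  expect_equal(porosity(50, 50), 0)
  expect_warning(phi1 <- porosity(100, 100 - 58.09), "clipped")
  expect_equal(phi1, 1)
  expect_error(porosity(10, 11), "exceeds")
})

test_that("tortuosity-corrected diffusivity matches its limiting cases", {
  expect_equal(sediment_diffusivity(1e-5, 1), 1e-5)
  expect_equal(sediment_diffusivity(1.0e-5, 0.75), 1e-5 / 1.75)
  expect_equal(sediment_diffusivity(1e-5, 0), 1e-5 / 4)
  expect_error(sediment_diffusivity(1e-5, 1.2), "phi")
  expect_error(sediment_diffusivity(0, 0.5), "d0")
})

test_that("the steady-state solver reproduces closed-form solutions", {
  z <- seq(0, 10, by = 0.1)
  # no consumption, fixed ends: Laplace -> exactly linear
  lin <- solve_steady_profile(z, 0, c(0, 10), 1e-5,
                              list(c_top = 300, c_bottom = 100))
  expect_equal(lin, seq(300, 100, length.out = length(z)), tolerance = 1e-10)
  # single zone, closed bottom: C(z) = R (L - z)^2 / (2 phiDs)
  C <- solve_steady_profile(z, 1e-5, c(0, 10), 1e-5,
                            list(c_bottom = 0, flux_bottom = 0))
  zc <- z / 10
  expect_equal(C, 1e-5 * (1 - zc)^2 / (2 * 1e-5), tolerance = 1e-9)
  expect_equal(C[1], 0.5, tolerance = 1e-9)
  expect_error(solve_steady_profile(z, 0, c(0, 10), 1e-5, list(c_top = 1)),
               "ill-posed")
})

test_that("two-zone solutions agree with the analytic piecewise quadratic", {
  zones <- c(0, 4, 12)
  rates <- c(3e-3, 6e-4)
  D <- c(8e-6, 7e-6)
  # closed bottom: lower zone C = R2 (L-z)^2 / (2 D2); upper zone continues
  # with matching concentration and flux at the interface
  L <- 1.2; b <- 0.4
  analytic <- function(z_mm) {
    zc <- z_mm / 10
    low <- rates[2] * (L - zc)^2 / (2 * D[2])
    cb <- rates[2] * (L - b)^2 / (2 * D[2])
    jb <- rates[2] * (L - b)
    up <- cb + jb * (b - zc) / D[1] + rates[1] * (b - zc)^2 / (2 * D[1])
    ifelse(zc < b, up, low)
  }
  z <- seq(0, 12, by = 0.2)
  C <- solve_steady_profile(z, rates, zones, D,
                            list(c_bottom = 0, flux_bottom = 0))
  expect_equal(C, analytic(z), tolerance = 1e-6)
  # and a coarse solve agrees with a 10x refined grid
  zf <- seq(0, 12, by = 0.02)
  Cd <- solve_steady_profile(z, rates, zones, D,
                             list(c_top = 250, c_bottom = 5))
  Cfd <- solve_steady_profile(zf, rates, zones, D,
                              list(c_top = 250, c_bottom = 5))
  expect_equal(Cd, Cfd[match(round(z, 6), round(zf, 6))], tolerance = 1e-6)
})

test_that("a noiseless profile inverts to its generating rates", {
  r <- simulate_o2_recovery(1, noise_sd = 0, max_zones = 4)
  expect_equal(r$fitted$n_zones, 2)
  expect_lt(max(abs(r$matched_rates - r$truth_rates) / r$truth_rates), 1e-3)
  # the single-zone analogue reduces from four zones to one
  r1 <- simulate_o2_recovery(2, noise_sd = 0, rates = 2e-3,
                             zones_mm = c(0, 15), max_zones = 4)
  expect_equal(r1$fitted$n_zones, 1)
  expect_lt(abs(r1$fitted$rates - 2e-3) / 2e-3, 1e-3)
})

test_that("a linear (zero-consumption) profile yields one zone of zero rate", {
  z <- c(seq(-5, -0.1, by = 0.1), seq(0, 15, by = 0.1))
  c_lin <- ifelse(z < 0, 300, 300 - 10 * z)
  fit <- fit_consumption_zones(list(z_mm = z, c = c_lin, phi = 0.9,
                                    d0 = 1.2e-5), max_zones = 4)
  expect_equal(fit$n_zones, 1)
  expect_equal(fit$rates, 0, tolerance = 1e-10)
})

test_that("depth-integrated consumption is conserved as SWI flux", {
  expect_equal(depth_integrated_rate(list(rates = 1e-5,
                                          boundaries_mm = c(0, 10))), 1e-5)
  expect_equal(depth_integrated_rate(list(rates = c(0, 0),
                                          boundaries_mm = c(0, 5, 10))), 0)
  r <- simulate_o2_recovery(3, noise_sd = 0)
  expect_equal(r$fitted$integrated_rate, sum(r$truth_rates * diff(c(0, 7.5, 15)) / 10),
               tolerance = 1e-3)
  # steady state, closed bottom: integral of R equals the downward SWI flux
  expect_equal(r$fitted$swi_flux, r$fitted$integrated_rate, tolerance = 1e-2)
})

test_that("noisy two-zone profiles recover rates within their standard errors", {
  hits <- 0; n <- 60
  for (s in 1:n) {
    r <- suppressWarnings(simulate_o2_recovery(s, noise_sd = 2, max_zones = 2))
    hits <- hits + all(abs(r$matched_rates - r$truth_rates) <= 2 * r$rate_se)
  }
  expect_gte(hits / n, 0.9)
})

test_that("fitted rates are stable under grid refinement", {
  cfg_fine <- scenario_config(seed = 9,
                              o2 = list(zones_mm = c(0, 7.5, 15),
                                        rates = c(5.57e-3, 1.115e-3),
                                        phi = 0.9, d0 = 1.2e-5, c_top = 300,
                                        noise_sd = 0, bc = "bottom_closed"))
  g <- gen_o2_profile(cfg_fine)
  fit_full <- fit_consumption_zones(g$profile, max_zones = 2,
                                    bc = "bottom_closed")
  half <- seq(1, length(g$profile$z_mm), by = 2)   # halve the resolution
  prof2 <- list(z_mm = g$profile$z_mm[half], c = g$profile$c[half],
                phi = 0.9, d0 = 1.2e-5)
  fit_half <- fit_consumption_zones(prof2, max_zones = 2,
                                    bc = "bottom_closed")
  expect_lt(max(abs(fit_half$rates - fit_full$rates) / fit_full$rates), 0.005)
})

test_that("penetration depth shrinks as single-zone consumption grows", {
  depths <- vapply(c(1e-3, 2e-3, 4e-3, 8e-3), function(R) {
    fit <- list(rates = R, boundaries_mm = c(0, 15),
                phi_ds = 0.9 * sediment_diffusivity(1.2e-5, 0.9),
                bclist = list(c_top = 300, c_bottom = 0),
                z_mm = seq(0, 15, by = 0.1))
    o2_penetration_depth(fit, threshold = 5)
  }, numeric(1))
  expect_true(all(diff(depths) < 0))
})

test_that("higher bottom-water O2 supports deeper, larger integrated consumption", {
  run <- function(c_top) {
    z <- seq(0, 15, by = 0.1)
    D <- 0.9 * sediment_diffusivity(1.2e-5, 0.9)
    # consumption scaled so oxygen is exhausted within the profile
    R <- 2 * D * c_top / 1.5^2
    C <- solve_steady_profile(z, R, c(0, 15), D,
                              list(c_bottom = 0, flux_bottom = 0))
    fit <- fit_consumption_zones(list(z_mm = z, c = C, phi = 0.9,
                                      d0 = 1.2e-5),
                                 max_zones = 2, bc = "bottom_closed")
    c(rate = fit$integrated_rate, pen = o2_penetration_depth(fit, 5))
  }
  summer <- run(320)   # oxygenated bottom water after melt
  spring <- run(80)
  expect_gt(summer["rate"], spring["rate"])
  expect_gt(summer["pen"], spring["pen"])
})

test_that("the D0 convenience table interpolates sensibly", {
  expect_equal(o2_diffusivity_d0(0), 1.10e-5)
  expect_gt(o2_diffusivity_d0(10), o2_diffusivity_d0(4))
  expect_equal(o2_diffusivity_d0(c(5, 25)), c(1.26e-5, 2.04e-5))
})
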