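test_that("slope fit reproduces an exact line and matches the normal-equations oracle", {
  s <- concentration_series(c(0, 60, 120), c(400, 460, 520), "co2", 298.15)
  f <- fit_slope(s)
  expect_equal(f$slope, 1)
  expect_equal(f$r_squared, 1)
  expect_equal(f$intercept, 400)

  # noisy series: agreement with brute-force OLS to 1e-10 relative, and
  # slope within 3 SE of the generating value
  set.seed(101)
  t <- 0:299
  y <- 1900 + 0.05 * t + rnorm(300, 0, 2)
  s2 <- concentration_series(t, y, "ch4", 300)
  f2 <- fit_slope(s2)
  o <- oracle_ols(t, y)
  expect_equal(f2$slope, o$slope, tolerance = 1e-10)
  expect_equal(f2$r_squared, o$r_squared, tolerance = 1e-10)
  expect_lt(abs(f2$slope - 0.05), 3 * o$se_slope)
})

test_that("degenerate and invalid series are handled explicitly", {
  flat <- concentration_series(0:9, rep(420, 10), "co2", 298.15)
  f <- fit_slope(flat)
  expect_equal(f$slope, 0)
  expect_true(is.na(f$r_squared))
  expect_error(fit_slope(concentration_series(0:1, c(1, 2), "co2", 298.15)),
               "3 points")
  expect_error(concentration_series(c(0, 0, 1), c(1, 2, 3), "co2", 298.15),
               "strictly increasing")
  expect_error(concentration_series(0:2, 1:3, "xenon", 298.15), "co2")
  expect_error(concentration_series(0:2, 1:3, "co2", -1), "kelvin")
})

test_that("QC rule rejects below threshold, passes at it, and flags flat series", {
  mk <- function(r2) structure(list(slope = 1, intercept = 0, r_squared = r2,
                                    n_points = 10L, gas = "co2", unit = "ppm"),
                               class = "slope_fit")
  expect_false(qc_filter(mk(0.69))$pass)
  expect_true(qc_filter(mk(0.70))$pass)
  expect_equal(qc_filter(mk(NA_real_))$reason, "degenerate")
  expect_equal(qc_filter(mk(0.2))$reason, "low_r_squared")
  # monotone in R^2: pass at r implies pass at any r' >= r
  rs <- sort(runif(50))
  passes <- vapply(rs, function(r) qc_filter(mk(r), threshold = 0.55)$pass,
                   logical(1))
  expect_true(all(diff(passes) >= 0))
})

test_that("flux conversion matches the dimensional-analysis oracle and is linear", {
  ch <- chamber_spec("soil_static", 6.4, 0.0707)
  s <- concentration_series(0:10, 400 + (0:10), "co2", 298.15)  # 1 ppm/s
  f <- compute_flux(fit_slope(s), ch, s)
  expect_equal(f$flux, oracle_flux(1, "co2", 6.4, 0.0707, 298.15),
               tolerance = 1e-12)

  # zero slope -> zero flux
  s0 <- concentration_series(0:10, rep(400, 11), "co2", 298.15)
  expect_equal(compute_flux(fit_slope(s0), ch, s0)$flux, 0)

  # doubling V doubles F; doubling A halves F
  ch2v <- chamber_spec("soil_static", 12.8, 0.0707)
  ch2a <- chamber_spec("soil_static", 6.4, 0.1414)
  expect_equal(compute_flux(fit_slope(s), ch2v, s)$flux, 2 * f$flux)
  expect_equal(compute_flux(fit_slope(s), ch2a, s)$flux, f$flux / 2,
               tolerance = 1e-12)

  # 100 random parameter draws against the oracle, 1e-9 relative
  set.seed(7)
  for (i in 1:100) {
    gas <- sample(c("co2", "ch4", "n2o"), 1)
    v <- runif(1, 0.5, 20); a <- runif(1, 0.01, 0.5)
    tk <- runif(1, 270, 320); slope <- runif(1, -2, 2)
    base <- if (gas == "co2") 420 else 1900
    si <- concentration_series(0:20, base + slope * (0:20), gas, tk)
    fi <- compute_flux(fit_slope(si), chamber_spec("soil_static", v, a), si)
    expect_equal(fi$flux, oracle_flux(slope, gas, v, a, tk),
                 tolerance = 1e-9)
  }
})

test_that("chamber geometry helpers compute area and headspace volume", {
  soil <- chamber_area_volume("soil_static", diameter_cm = 30,
                              cover_volume_l = 6.4)
  expect_equal(soil$area_m2, pi * 0.15^2, tolerance = 1e-9)
  expect_equal(soil$area_m2, 0.070686, tolerance = 1e-4)
  # 16 cm ring inserted 10 cm: cylinder of 6 cm above soil adds
  # pi * 0.15^2 * 0.06 m^3 of headspace
  expect_equal(soil$volume_l, 6.4 + pi * 0.15^2 * 0.06 * 1000,
               tolerance = 1e-9)

  stem <- chamber_area_volume("stem_semirigid", arc_cm = 20, height_cm = 25,
                              volume_l = 1.5)
  expect_equal(stem$area_m2, 0.05)

  expect_error(chamber_area_volume("soil_static", cover_volume_l = 6.4),
               "diameter_cm")
  expect_error(chamber_spec("soil_static", -1, 0.07), "volume")
})

test_that("flux_table batches deployments with provenance and QC reasons", {
  ch <- chamber_spec("stem_semirigid", 1.5, 0.05)
  good <- series_with_r2(0.95, slope = 0.5, gas = "ch4", chamber_id = "d1")
  bad <- series_with_r2(0.30, slope = 0.5, gas = "ch4", chamber_id = "d2")
  meta <- data.frame(chamber_id = c("d1", "d2"), site = "S1",
                     tree = c("t1", "t2"), season = "summer",
                     surface = "stem", stringsAsFactors = FALSE)
  tab <- flux_table(list(good, bad), ch, meta)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$qc_pass, c(TRUE, FALSE))
  expect_equal(tab$qc_reason, c("ok", "low_r_squared"))
  expect_equal(tab$site, c("S1", "S1"))
  expect_equal(tab$tree, c("t1", "t2"))
})
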