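geo2 <- tree_geometry("t1", c(0, 0.4), c(0.4, 0.85), c(0.3, 0.3))

test_that("per-tree flux is the lateral-area weighted sum of interval fluxes", {
  g1 <- tree_geometry("u", 0, 1, 1)          # P x H = 1 m^2
  expect_equal(per_tree_flux(5, g1), 5)
  expect_equal(per_tree_flux(c(0, 0), geo2), 0)
  # hand sum: 2 * 0.12 + (-1) * 0.135
  expect_equal(per_tree_flux(c(2, -1), geo2), 0.105)
  expect_error(per_tree_flux(c(1, 2, 3), geo2), "interval")
  # linearity in k
  f <- c(1.3, -0.2)
  expect_equal(per_tree_flux(3 * f, geo2), 3 * per_tree_flux(f, geo2))
})

test_that("stem-area weighting normalizes and preserves the weighted-mean identity", {
  expect_equal(stem_area_weighted(10, 2), 5)
  expect_equal(stem_area_weighted(0.105, 0.255), 0.105 / 0.255)
  expect_equal(stem_area_weighted(0.105, 0.255), 0.4118, tolerance = 1e-4)
  # uniform interval flux with A_t = sum(P H) recovers the flux
  f <- 2.5
  ft <- per_tree_flux(c(f, f), geo2)
  expect_equal(stem_area_weighted(ft, sum(geo2$lateral_area_m2)), f)
  # and F_ta always lies within the interval flux range then
  set.seed(1)
  for (i in 1:20) {
    fx <- rnorm(2)
    fta <- stem_area_weighted(per_tree_flux(fx, geo2),
                              sum(geo2$lateral_area_m2))
    expect_gte(fta, min(fx)); expect_lte(fta, max(fx))
  }
  expect_error(stem_area_weighted(1, 0), "> 0")
})

test_that("forest-area-weighted annualization follows the seasonal closed forms", {
  # constant flux, 4 seasons, default calendar
  expect_equal(forest_area_weighted_stem(rep(1, 4), 1000), 8.76)
  expect_equal(forest_area_weighted_stem(rep(0, 4), 1000), 0)
  # two-season split of the 8760-h year
  expect_equal(forest_area_weighted_stem(c(1, 3), 100, 4380), 1.752)
  expect_error(forest_area_weighted_stem(numeric(0), 100), "empty")

  expect_equal(forest_area_weighted_soil(rep(1, 4)), 87.6)
  expect_equal(forest_area_weighted_soil(rep(0, 4)), 0)
  expect_equal(forest_area_weighted_soil(c(0.5, 1, 2, 0.5)), 87.6)

  # linearity: scaling all seasonal fluxes scales the annual flux
  f <- c(0.2, 1.4, 2.2, 0.8)
  expect_equal(forest_area_weighted_stem(5 * f, 800),
               5 * forest_area_weighted_stem(f, 800))
})

test_that("ecosystem totals and stem contributions handle opposing signs", {
  e <- ecosystem_flux(42.56, -0.05)
  expect_equal(e$total, 42.51)
  expect_equal(e$stem_contribution_pct, 100.1, tolerance = 1e-3)
  expect_equal(ecosystem_flux(0, 5)$stem_contribution_pct, 0)
  expect_equal(ecosystem_flux(1, 1)$stem_contribution_pct, 50)
  expect_true(is.na(ecosystem_flux(1, -1)$stem_contribution_pct))
})

test_that("vertical contributions sum to 100% and allow negative shares", {
  g4 <- tree_geometry("e", c(0, 1, 2, 3), c(1, 2, 3, 4), rep(1, 4))
  expect_equal(vertical_contributions(rep(2, 4), g4), rep(25, 4))
  expect_equal(vertical_contributions(c(2, -1), geo2),
               c(228.5714, -128.5714), tolerance = 1e-4)
  set.seed(2)
  for (i in 1:25) {
    fx <- rnorm(4)
    expect_equal(sum(vertical_contributions(fx, g4)), 100, tolerance = 1e-9)
  }
  expect_true(all(is.na(vertical_contributions(c(0, 0), geo2))))
})

test_that("seasonal summaries report shares of the annual flux", {
  one <- data.frame(season = "summer", flux = c(1, 2, 3))
  expect_equal(seasonal_summary(one)$share_pct, 100)
  sym <- data.frame(season = c("winter", "summer"), flux = c(1, -1))
  expect_true(all(is.na(seasonal_summary(sym)$share_pct)))
  four <- data.frame(season = rep(c("winter", "spring", "summer", "autumn"),
                                  each = 2),
                     flux = rep(c(2, 1, 1, 0), each = 2))
  ss <- seasonal_summary(four)
  expect_equal(ss$share_pct[match(c("winter", "spring", "summer", "autumn"),
                                  ss$season)],
               c(50, 25, 25, 0))
  expect_equal(ss$n, rep(2L, 4))
})

test_that("noise-free campaigns upscale to the truth-table annual fluxes", {
  camp <- simulate_campaign(tiny_campaign_config(noise_sd = 0))
  chambers <- stats::setNames(
    lapply(camp$meta$surface,
           function(s) if (s == "stem") camp$stem_chamber else camp$soil_chamber),
    camp$meta$chamber_id)
  tab <- flux_table(camp$series, chambers, camp$meta)
  got <- site_annual_fluxes(tab, camp$geometry, camp$sites$density[1])

  # same aggregation applied to the true fluxes in the truth table
  tr <- camp$truth
  for (g in unique(got$gas)) {
    stem <- tr[tr$gas == g & tr$surface == "stem", ]
    ft_s <- sapply(unique(stem$season), function(s) {
      mean(sapply(unique(stem$tree), function(tn) {
        st <- stem[stem$season == s & stem$tree == tn, ]
        geo <- camp$geometry[[tn]]
        labels <- paste0(geo$height_low_m, "-", geo$height_high_m)
        per_tree_flux(st$true_flux[match(labels, st$height_interval)], geo)
      }))
    })
    want_taw <- forest_area_weighted_stem(ft_s, camp$sites$density[1])
    expect_equal(got$f_taw[got$gas == g], want_taw, tolerance = 1e-6)
    soil <- tr[tr$gas == g & tr$surface == "soil", ]
    ms <- sapply(unique(soil$season),
                 function(s) mean(soil$true_flux[soil$season == s]))
    expect_equal(got$f_saw[got$gas == g], forest_area_weighted_soil(ms),
                 tolerance = 1e-6)
  }
})
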