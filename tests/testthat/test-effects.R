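# Point-mass "draws" at the published posterior means, for contrast algebra.
table1_point_draws <- function(n = 3) {
  truth <- truth_parameters("table1")
  matrix(rep(truth$beta, each = n), n, 19,
         dimnames = list(NULL, names(truth$beta)))
}

test_that("marginal temperature effects are the documented contrasts", {
  pm <- table1_point_draws()

  # baseline species out of water: the contrast is the Temp term itself
  base <- marginal_temperature_effect(pm, "X.tropicalis", water = 0)
  expect_equal(base$mean, -0.0092)
  expect_equal(base$draws, pm[, "Temp"], ignore_attr = TRUE)

  # R. marina in water: sum of four published means
  rmw <- marginal_temperature_effect(pm, "R.marina", water = 1)
  expect_equal(rmw$mean, -0.0092 - 0.0057 + 0.0028 + 0.0074,
               tolerance = 1e-12)
  expect_equal(rmw$mean, -0.0047, tolerance = 1e-12)

  # P. terribilis out of water
  ptn <- marginal_temperature_effect(pm, "P.terribilis", water = 0)
  expect_equal(ptn$mean, -0.0092 - 0.0092, tolerance = 1e-12)

  expect_error(marginal_temperature_effect(pm, "R.catesbeiana", 0),
               "unknown species")
})

test_that("contrast means equal contrasts of means (linearity)", {
  draws <- withr::with_seed(11, {
    m <- matrix(stats::rnorm(19 * 500, sd = 0.01), 500, 19,
                dimnames = list(NULL, ewl_terms()))
    m
  })
  for (sp in ewl_species_levels()) {
    for (w in 0:1) {
      e <- marginal_temperature_effect(draws, sp, w)
      means <- colMeans(draws)
      expected <- means[["Temp"]]
      if (sp != "X.tropicalis") {
        expected <- expected + means[[paste0(sp, "-Temp")]]
      }
      if (w == 1) {
        expected <- expected + means[["Water-Temp"]]
        if (sp != "X.tropicalis") {
          expected <- expected + means[[paste0(sp, "-Water-Temp")]]
        }
      }
      expect_equal(e$mean, expected, tolerance = 1e-12)
    }
  }
})

test_that("direction probabilities count negative draws", {
  expect_equal(prob_direction(c(-1, -2, -0.5)), 1)
  expect_equal(prob_direction(c(-1, 1, -2, 2)), 0.5)
  expect_equal(prob_direction(c(-1, 0, 1, 0)), 0.5)  # ties count half

  # normal draws matching the published Temp posterior: the implied
  # closed-form tail is pnorm(0.0092 / 0.0059)
  p <- withr::with_seed(13, {
    prob_direction(stats::rnorm(1e6, -0.0092, 0.0059))
  })
  expect_equal(p, stats::pnorm(0.0092 / 0.0059), tolerance = 0.002)
})

test_that("rate conversions reproduce the published arithmetic", {
  expect_equal(round(percent_per_minute(0.0023), 2), 0.23)
  expect_equal(percent_per_minute(0), 0)
  expect_equal(round(percent_per_minute(0.1383), 2), 14.83)
  expect_equal(round(abs(percent_per_minute(-0.0019)), 1), 0.2)
  expect_equal(round(abs(percent_per_minute(-0.0002)), 2), 0.02)

  expect_equal(round(abs(mass_rate(-0.0002, 165))), 33)
  expect_equal(mass_rate(0, 10), 0)
  expect_equal(mass_rate(-0.0019, 13.5), -25.6, tolerance = 0.05)
  expect_error(mass_rate(0.001, -5), "reference_mass_g")

  # consistency: mass_rate per unit mass is percent_per_minute
  for (b in c(-0.004, 0, 0.002)) {
    expect_equal(mass_rate(b, 37) / 37 / 10, percent_per_minute(b),
                 tolerance = 1e-12)
  }
})

test_that("variance ratios round to the published 20/40/65", {
  summ <- data.frame(term = c("species", "housing", "date", "frog"),
                     mean = c(5.1479, 0.2555, 0.1280, 0.0787))
  expect_equal(variance_ratio(summ, "species", "housing")$nearest_integer, 20)
  expect_equal(variance_ratio(summ, "species", "date")$nearest_integer, 40)
  expect_equal(variance_ratio(summ, "species", "frog")$nearest_integer, 65)
  eq <- data.frame(term = c("a", "b"), mean = c(0.3, 0.3))
  expect_equal(variance_ratio(eq, "a", "b")$ratio, 1)
  zero <- data.frame(term = c("a", "b"), mean = c(0.3, 0))
  expect_error(variance_ratio(zero, "a", "b"), "zero denominator")
  expect_error(variance_ratio(summ, "species", "cage"), "not found")
})

test_that("outcome classification follows the rule table", {
  slope_row <- function(w, tc, m, half) {
    data.frame(water = w, temp_c = tc, mean = m, lo = m - half,
               hi = m + half)
  }
  # small water effect, no temperature interaction, gain in water: O1
  o1 <- rbind(slope_row(1, 26, 0.001, 0.0005),
              slope_row(0, 26, -0.002, 0.0005),
              slope_row(1, 36, 0.0009, 0.0005),
              slope_row(0, 36, -0.0021, 0.0005))
  expect_equal(classify_outcome(o1)$label, "O1")

  # identical slopes in and out of water: O2
  o2 <- rbind(slope_row(1, 26, -0.002, 0.0005),
              slope_row(0, 26, -0.002, 0.0005))
  expect_equal(classify_outcome(o2)$label, "O2")

  # strong interaction, slight gain in water, strong loss without: O3
  o3 <- rbind(slope_row(1, 26, 0.0005, 0.0002),
              slope_row(0, 26, -0.004, 0.0002),
              slope_row(1, 36, -0.0002, 0.0002),
              slope_row(0, 36, -0.006, 0.0002))
  expect_equal(classify_outcome(o3)$label, "O3")

  # loss even in water, no interaction: O4
  o4 <- rbind(slope_row(1, 26, -0.001, 0.0004),
              slope_row(0, 26, -0.003, 0.0004))
  expect_equal(classify_outcome(o4)$label, "O4")

  # loss in water with an interaction: O5
  o5 <- rbind(slope_row(1, 26, -0.002, 0.0002),
              slope_row(0, 26, -0.004, 0.0002),
              slope_row(1, 36, -0.004, 0.0002),
              slope_row(0, 36, -0.007, 0.0002))
  expect_equal(classify_outcome(o5)$label, "O5")

  # invariance to a common rescaling of the time unit
  rescale <- o3
  rescale[, c("mean", "lo", "hi")] <- rescale[, c("mean", "lo", "hi")] * 60
  expect_equal(classify_outcome(rescale)$label,
               classify_outcome(o3)$label)

  expect_error(classify_outcome(slope_row(1, 26, 0, 0.1)), "required")
})
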