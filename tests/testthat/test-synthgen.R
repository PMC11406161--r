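test_that("designs are balanced over the treatment grid", {
  d <- make_design(8, profiles = species_profiles()["X.tropicalis"], seed = 1)
  expect_equal(nrow(d), 32)
  expect_equal(unname(table(paste(d$water, d$temp_c))),
               as.integer(rep(8, 4)), ignore_attr = TRUE)

  d3 <- make_design(1, seed = 2)
  expect_equal(nrow(d3), 12)

  # balance property across a range of cell sizes
  for (n in c(1, 3, 8)) {
    d <- make_design(n, seed = n)
    cell <- table(d$species, paste(d$water, d$temp_c))
    expect_lte(max(cell) - min(cell), 1)
  }

  # SVL stays within the species range
  prof <- species_profiles()
  d <- make_design(8, seed = 9)
  for (p in prof) {
    svl <- d$svl_mm[d$species == p$name]
    expect_true(all(svl >= p$svl_range_mm[1] & svl <= p$svl_range_mm[2]))
  }

  expect_error(make_design(8, profiles = list()), "at least one species")
})

test_that("same seed reproduces identical designs and experiments", {
  expect_identical(make_design(4, seed = 7), make_design(4, seed = 7))
  truth <- truth_parameters("table1")
  design <- make_design(2, seed = 7)
  e1 <- simulate_experiment(design, truth, seed = 11)
  e2 <- simulate_experiment(design, truth, seed = 11)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
})

test_that("study-scale design has 95 individuals (32/32/31)", {
  d <- study_design(seed = 1)
  expect_equal(nrow(d), 95)
  expect_equal(sort(as.integer(table(d$species))), c(31L, 32L, 32L))
})

test_that("noise-free trajectories reproduce the linear predictor", {
  # pure dehydration: ln-mass drop over 60 min is exactly rate * 60
  truth <- deterministic_truth(Time = -0.0019, Intercept = log(13.5))
  s <- simulate_series(baseline_individual(water = 0), truth,
                       times = c(0, 60), seed = 1)
  expect_equal(log(s$mass_g[1]) - log(s$mass_g[2]), 0.0019 * 60,
               tolerance = 1e-12)

  # in water the uptake slope adds to the dehydration slope
  truth2 <- deterministic_truth(Time = -0.0019, "Water-Time" = 0.0023,
                                Intercept = log(13.5))
  sw <- simulate_series(baseline_individual(water = 1), truth2,
                        times = c(0, 60), seed = 1)
  net <- (log(sw$mass_g[2]) - log(sw$mass_g[1])) / 60
  expect_equal(net, -0.0019 + 0.0023, tolerance = 1e-12)

  # single time point: series of length 1 at the starting mass
  s0 <- simulate_series(baseline_individual(), truth, times = 0, seed = 1)
  expect_equal(nrow(s0), 1)
  expect_equal(s0$mass_g, 13.5, tolerance = 1e-12)

  # full linear predictor reproduction across random individuals
  truth3 <- truth_parameters("table1")
  truth3$variances[] <- 0
  design <- make_design(2, seed = 5)
  for (i in seq_len(nrow(design))) {
    ind <- design[i, ]
    s <- simulate_series(ind, truth3, times = c(0, 20, 40, 60), seed = i)
    lp <- ewlmm:::linear_predictor(ind$species, ind$water, ind$temp_c,
                                   c(0, 20, 40, 60), ind$svl_mm, truth3)
    expect_equal(log(s$mass_g), lp, tolerance = 1e-10)
  }

  expect_error(simulate_series(baseline_individual(), truth,
                               times = c(0, 20, 20)), "strictly increasing")
})

test_that("residual autocorrelation at lag 20 matches the kernel", {
  truth <- deterministic_truth(Intercept = log(13.5))
  truth$variances[["error"]] <- 0.0174
  ind <- baseline_individual()
  n <- 2000
  resid <- withr::with_seed(42, {
    t(vapply(seq_len(n), function(i) {
      s <- simulate_series(ind, truth, times = c(0, 20, 40, 60))
      log(s$mass_g) - log(13.5)
    }, numeric(4)))
  })
  lag20 <- cor(c(resid[, 1:3]), c(resid[, 2:4]))
  expect_equal(lag20, temporal_correlation(20, 0.5), tolerance = 0.05)
})

test_that("truth presets reproduce the published coefficient table", {
  t1 <- truth_parameters("table1")
  expect_equal(t1$beta[["Time"]], -0.0019)
  expect_equal(t1$beta[["SVL"]], 0.1383)
  expect_equal(t1$variances[["species"]], 5.1479)
  expect_length(t1$beta, 19)

  t0 <- truth_parameters("null")
  expect_true(all(t0$beta[setdiff(ewl_terms(), "Intercept")] == 0))

  # no marginal water effect: in-water slope equals the no-water slope
  o2 <- truth_parameters("fig1:O2")
  expect_equal(o2$beta[["Water-Time"]], 0)
  expect_equal(o2$beta[["Water"]], 0)

  expect_error(truth_parameters("fig1:O9"), "unknown truth preset")
})

test_that("corruption applies excretion, dropout and masking as specified", {
  truth <- deterministic_truth(Intercept = log(10))
  s <- simulate_series(baseline_individual(), truth,
                       times = c(0, 20, 40, 60), seed = 1)

  # probabilities zero: identity
  expect_identical(
    as.data.frame(corrupt_series(s, excretion_prob = 0, missing_prob = 0,
                                 seed = 1)),
    as.data.frame(s))

  # forced 2% excretion of a 10 g frog at the second time point
  ce <- corrupt_series(s, excretion_prob = 0, missing_prob = 0, seed = 1,
                       force_excretion = list(index = 2, frac = 0.02))
  expect_equal(ce$mass_g[1], 10)
  expect_equal(ce$mass_g[2:4], s$mass_g[2:4] - 0.2, tolerance = 1e-12)
  expect_equal(ce$excreted_g[2], 0.2, tolerance = 1e-12)

  # a trajectory crossing 20% loss is truncated from the crossing on
  steep <- deterministic_truth(Time = -0.005, Intercept = log(10))
  sd_ <- simulate_series(baseline_individual(), steep,
                         times = c(0, 20, 40, 60), seed = 1)
  expect_gt(1 - sd_$mass_g[4] / sd_$mass_g[1], 0.25)
  cd <- corrupt_series(sd_, excretion_prob = 0, missing_prob = 0,
                       dropout_threshold = 0.2, seed = 1)
  expect_true(attr(cd, "dropout"))
  expect_equal(cd$status[4], "truncated")
  kept <- cd$time_min[cd$status != "truncated"]
  expect_lt(max(kept), 60)

  expect_error(corrupt_series(s, dropout_threshold = 0), "dropout_threshold")
  expect_error(corrupt_series(s, excretion_frac_range = c(0.03, 0.005)),
               "excretion_frac_range")
})

test_that("experiment CSV round-trips and truth JSON round-trips", {
  fx <- small_experiment(n_per_treatment = 1)
  ex <- corrupt_experiment(fx$experiment, missing_prob = 0.2, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_experiment_csv(ex, path)
  back <- read_experiment_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ex), tolerance = 1e-10)

  jpath <- withr::local_tempfile(fileext = ".json")
  write_truth_json(fx$truth, jpath)
  tr <- read_truth_json(jpath)
  expect_equal(tr$beta, fx$truth$beta)
  expect_equal(tr$variances, fx$truth$variances)

  # externally named columns load through the column map, with optional
  # provenance columns defaulted
  df <- utils::read.csv(path)
  names(df)[names(df) == "svl_mm"] <- "SVL"
  df$excreted_g <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE)
  mapped <- read_experiment_csv(path2, column_map = c(svl_mm = "SVL"))
  expect_equal(mapped$design$svl_mm, back$design$svl_mm, tolerance = 1e-9)
  expect_true(all(vapply(mapped$series,
                         function(s) all(s$excreted_g == 0), logical(1))))
  expect_error(read_experiment_csv(path2, column_map = c(mass_g = "Mass")),
               "Mass")
})
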