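test_that("design matrix follows the canonical 19-term coding", {
  design <- data.frame(id = c("a", "b"),
                       species = c("X.tropicalis", "R.marina"),
                       svl_mm = c(34, 155), housing = c("h1", "h2"),
                       date = c("d1", "d1"), water = c(0L, 1L),
                       temp_c = c(26, 36), stringsAsFactors = FALSE)
  series <- list(mass_series("a", 0, 13.5),
                 mass_series("b", c(0, 30), c(165, 164)))
  fr <- build_model_frame(series, design)
  X <- design_matrix(fr)
  expect_equal(ncol(X), 19)
  expect_equal(colnames(X), ewl_terms())

  # baseline frog at t=0, 26 degC, midpoint SVL: only the intercept is set
  expect_equal(unname(X[1, ]), c(1, rep(0, 18)))

  # R. marina in water at t=30: product coding of the interactions
  row <- X[3, ]
  expect_equal(unname(row[["Water-Time"]]), 30)
  expect_equal(unname(row[["R.marina-Water-Time"]]), 30)
  expect_equal(unname(row[["R.marina-Water"]]), 1)
  expect_equal(unname(row[["Water-Temp"]]), 10)

  bad <- fr
  bad$species[1] <- "L.catesbeianus"
  expect_error(design_matrix(bad), "unknown species")
})

test_that("default priors encode the documented construction rules", {
  pri <- default_priors()
  # uptake prior mean is minus twice the pilot dehydration rate
  expect_equal(pri$beta_mean[["Time"]], -0.002)
  expect_equal(pri$beta_mean[["Water-Time"]], 0.004)
  # every normal prior keeps zero within two sd of the mean
  expect_true(all(abs(pri$beta_mean) / pri$beta_sd <= 2))
  # body-size information enters at the ln range midpoints
  expect_equal(pri$svl_midpoint_ln[["X.tropicalis"]], log((28 + 40) / 2))
  # narrow error variance prior, wide group variance priors
  expect_equal(unname(pri$variance_shape[["error"]]), 3)
  expect_equal(unname(pri$variance_scale[["error"]]), 0.05)
  expect_equal(unname(pri$variance_shape[["frog"]]), 2)
  # water-temperature interaction scaled by surface coverage fractions
  expect_equal(pri$beta_mean[["Water-Temp"]], -0.5 * -0.005)
  expect_equal(pri$beta_mean[["R.marina-Water-Temp"]], (0.5 - 0.25) * -0.005)
})

test_that("log posterior matches an independent dense Gaussian evaluation", {
  fx <- small_experiment(n_per_treatment = 1, seed = 23)
  fr <- fx$frame[1:6, ]
  attributes(fr)[c("coding", "svl_centers", "class")] <-
    attributes(fx$frame)[c("coding", "svl_centers", "class")]
  phi <- ewlmm:::default_phylo_correlation()
  truth <- fx$truth
  theta <- c(truth$beta, truth$variances, rho = 0.4)

  lp <- log_posterior(theta, fr, phi)

  # brute-force multivariate normal density via solve() and det()
  sigma <- residual_covariance(fr, phi, list(rho = 0.4), truth$variances)
  X <- design_matrix(fr)
  r <- fr$ln_mass - drop(X %*% truth$beta)
  brute <- -0.5 * 6 * log(2 * pi) - 0.5 * log(det(sigma)) -
    0.5 * drop(t(r) %*% solve(sigma) %*% r)
  expect_equal(lp, brute, tolerance = 1e-8)

  # translation invariance: shifting ln mass and the intercept together
  fr2 <- fr
  fr2$ln_mass <- fr$ln_mass + 3
  theta2 <- theta
  theta2[["Intercept"]] <- theta[["Intercept"]] + 3
  expect_equal(log_posterior(theta2, fr2, phi), lp, tolerance = 1e-8)

  # out-of-support parameters: -Inf, not an exception
  theta_bad <- theta
  theta_bad[["error"]] <- -1
  expect_identical(log_posterior(theta_bad, fr, phi), -Inf)
  theta_bad2 <- theta
  theta_bad2[["rho"]] <- 1.5
  expect_identical(log_posterior(theta_bad2, fr, phi), -Inf)
})

test_that("compiled likelihood and gradient match the R reference", {
  # one individual per species with well-spread times keeps both
  # covariance modes well conditioned, so the two computational routes
  # can be compared tightly
  design <- data.frame(
    id = c("xt1", "rm1", "pt1"),
    species = c("X.tropicalis", "R.marina", "P.terribilis"),
    svl_mm = c(34, 150, 46), housing = c("h1", "h2", "h3"),
    date = c("d1", "d1", "d2"), water = c(0L, 1L, 0L),
    temp_c = c(26, 36, 26), stringsAsFactors = FALSE)
  times <- list(c(0, 18, 43, 61), c(0, 24, 39, 58), c(0, 21, 37, 63))
  truth <- truth_parameters("table1")
  series <- withr::with_seed(29, lapply(seq_len(3), function(i) {
    simulate_series(design[i, ], truth, times[[i]])
  }))
  fr <- build_model_frame(series, design)
  phi <- ewlmm:::default_phylo_correlation()
  X <- design_matrix(fr)
  for (mode in c("nested", "composite")) {
    str <- ewlmm:::covariance_structures(fr, phi, mode, 20)
    ptr <- ewlmm:::ewl_model_build(X, fr$ln_mass, str$W, str$D2, str$S_frog,
                                   str$S_housing, str$S_date, str$S_species,
                                   1e-8)
    cc <- ewlmm:::ewl_model_lpgrad(ptr, truth$beta, truth$variances, 0.5)
    theta <- c(truth$beta, truth$variances, rho = 0.5)
    expect_equal(cc$ll, log_posterior(theta, fr, phi, mode = mode),
                 tolerance = 1e-9)

    # finite-difference gradient spot checks
    fd <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
    g_time <- fd(function(b) {
      bb <- truth$beta; bb[["Time"]] <- b
      ewlmm:::ewl_model_lpgrad(ptr, bb, truth$variances, 0.5)$ll
    }, truth$beta[["Time"]], 1e-7)
    expect_equal(cc$gbeta[2], g_time, tolerance = 1e-4)
    g_sp <- fd(function(x) {
      vv <- truth$variances; vv[["species"]] <- x
      ewlmm:::ewl_model_lpgrad(ptr, truth$beta, vv, 0.5)$ll
    }, truth$variances[["species"]], 1e-5)
    expect_equal(cc$gv[4], g_sp, tolerance = 1e-4)
    g_rho <- fd(function(x) {
      ewlmm:::ewl_model_lpgrad(ptr, truth$beta, truth$variances, x)$ll
    }, 0.5, 1e-6)
    expect_equal(cc$grho, g_rho, tolerance = 1e-4)
  }
})

test_that("marginalised likelihood equals explicit random-effect integration", {
  # two frogs of one species sharing housing and date: the shared effects
  # collapse to one scalar, leaving a 3-dimensional integral
  design <- data.frame(id = c("a", "b"), species = "X.tropicalis",
                       svl_mm = 34, housing = "h1", date = "d1",
                       water = 0L, temp_c = 26, stringsAsFactors = FALSE)
  series <- list(mass_series("a", c(0, 20), c(13.4, 13.3)),
                 mass_series("b", c(0, 20), c(13.6, 13.5)))
  fr <- build_model_frame(series, design)
  phi <- diag(1)
  dimnames(phi) <- list("X.tropicalis", "X.tropicalis")
  v <- c(frog = 0.04, housing = 0.01, date = 0.02, species = 0.09,
         error = 0.005)
  beta <- stats::setNames(numeric(19), ewl_terms())
  beta[["Intercept"]] <- log(13.5)
  rho <- 0.6
  theta <- c(beta, v, rho = rho)
  lp <- log_posterior(theta, fr, phi, mode = "nested")

  X <- design_matrix(fr)
  mu <- drop(X %*% beta)
  Ke <- v[["error"]] *
    outer(c(0, 20), c(0, 20),
          function(a, b) temporal_correlation(abs(a - b), rho)) +
    diag(1e-8, 2)
  v_shared <- v[["housing"]] + v[["date"]] + v[["species"]]
  gh <- pracma::gaussHermite(120)
  nodes <- sqrt(2) * gh$x
  wts <- gh$w / sqrt(pi)
  dens_frog <- function(y, m, u) {
    # integrate the frog effect for one animal given the shared effect u
    vals <- vapply(seq_along(nodes), function(i) {
      uf <- nodes[i] * sqrt(v[["frog"]])
      exp(ewlmm:::ldmvn(y, m + u + uf, Ke))
    }, numeric(1))
    sum(wts * vals)
  }
  total <- 0
  for (i in seq_along(nodes)) {
    u <- nodes[i] * sqrt(v_shared)
    total <- total + wts[i] *
      dens_frog(fr$ln_mass[1:2], mu[1:2], u) *
      dens_frog(fr$ln_mass[3:4], mu[3:4], u)
  }
  expect_equal(lp, log(total), tolerance = 1e-6)
})

test_that("GLS oracle matches ordinary least squares and direct solves", {
  fx <- small_experiment(n_per_treatment = 2, seed = 37)
  fr <- fx$frame
  X <- design_matrix(fr)

  # identity covariance: OLS
  g <- gls_fit(fr, diag(nrow(fr)))
  ols <- stats::lm.fit(X, fr$ln_mass)$coefficients
  expect_equal(unname(g$coefficients), unname(ols), tolerance = 1e-8)

  # duplicated rows with halved variance give the same estimates
  fr2 <- rbind(fr, fr)
  attributes(fr2)[c("coding", "svl_centers", "class")] <-
    attributes(fr)[c("coding", "svl_centers", "class")]
  g2 <- gls_fit(fr2, diag(0.5, 2 * nrow(fr)))
  expect_equal(g2$coefficients, g$coefficients, tolerance = 1e-8)

  # general covariance: direct solve of the normal equations
  phi <- ewlmm:::default_phylo_correlation()
  sigma <- residual_covariance(fr, phi, list(rho = 0.5),
                               fx$truth$variances)
  g3 <- gls_fit(fr, sigma)
  Si <- solve(sigma)
  direct <- solve(t(X) %*% Si %*% X, t(X) %*% Si %*% fr$ln_mass)
  expect_equal(unname(g3$coefficients), unname(drop(direct)),
               tolerance = 1e-6)

  # singular designs name the collinear column
  frs <- fr[fr$species == "X.tropicalis" & fr$water == 0, ]
  attributes(frs)[c("coding", "svl_centers", "class")] <-
    attributes(fr)[c("coding", "svl_centers", "class")]
  expect_error(gls_fit(frs, diag(nrow(frs))), "collinear")
})

test_that("posterior summaries report means, intervals and zero exclusion", {
  const <- matrix(2.5, 100, 1, dimnames = list(NULL, "Time"))
  s <- summarize_posterior(const)
  expect_equal(s$mean, 2.5)
  expect_equal(s$q2.5, 2.5)
  expect_equal(s$q97.5, 2.5)
  expect_true(s$excludes_zero)

  sym <- matrix(c(-1, 1, -2, 2), 4, 1, dimnames = list(NULL, "x"))
  expect_false(summarize_posterior(sym)$excludes_zero)

  z <- withr::with_seed(5, matrix(stats::rnorm(1e5), ncol = 1,
                                  dimnames = list(NULL, "z")))
  sz <- summarize_posterior(z)
  expect_equal(sz$q2.5, -1.96, tolerance = 0.02)
  expect_equal(sz$q97.5, 1.96, tolerance = 0.02)
})

test_that("posterior concentrates on the GLS solution under flat priors", {
  # moderate fixture: fixed covariance, flat priors, short chains
  fx <- small_experiment(n_per_treatment = 2, seed = 41)
  phi <- ewlmm:::default_phylo_correlation()
  v <- fx$truth$variances
  fit <- fit_hmc(fx$frame, phi, priors = NULL, chains = 2, warmup = 500,
                 samples = 500, seed = 3,
                 fixed = list(variances = v, rho = 0.5))
  sigma <- residual_covariance(fx$frame, phi, list(rho = 0.5), v)
  g <- gls_fit(fx$frame, sigma)
  s <- summarize_posterior(fit)
  for (i in seq_len(19)) {
    p <- s$term[i]
    d <- fit$draws[, , p]
    mcse <- stats::sd(d) / sqrt(ewlmm:::ess_mean(d))
    expect_lt(abs(s$mean[i] - g$coefficients[[p]]), 4 * mcse)
  }
  expect_lt(max(fit$diagnostics$rhat), 1.1)
})
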