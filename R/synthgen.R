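#' Build a balanced experimental design
#'
#' Lays out individuals for each species over the 2x2 water x temperature
#' grid, mirroring the study's schedule: treatments cycle within each
#' measurement date so that each date holds one animal per treatment (4
#' frogs/date), dates accumulate until the species' quota is filled (8 dates
#' at the default 8 animals per treatment), housing tanks alternate
#' cyclically within species, and SVL is drawn uniformly within the species
#' range.
#'
#' @param n_per_treatment Animals per treatment cell per species (>= 1).
#' @param profiles List of [species_profile()] objects (>= 1).
#' @param seed Integer seed; the same seed reproduces the same design.
#' @param temperatures Two incubation temperatures in degC.
#' @param n_housing Housing tanks per species.
#' @param frogs_per_date Animals measured per date (per species).
#' @return A data frame with one row per individual: `id`, `species`,
#'   `svl_mm`, `housing`, `date`, `water`, `temp_c`.
#' @export
make_design <- function(n_per_treatment, profiles = species_profiles(),
                        seed = 1, temperatures = c(26, 36),
                        n_housing = 2, frogs_per_date = 4) {
  if (length(profiles) < 1) {
    stop("at least one species profile is required", call. = FALSE)
  }
  if (n_per_treatment < 1) stop("n_per_treatment must be >= 1", call. = FALSE)
  trt <- expand.grid(water = c(0L, 1L), temp_c = temperatures)
  with_seed(seed, {
    rows <- lapply(profiles, function(p) {
      n <- n_per_treatment * nrow(trt)
      idx <- seq_len(n)
      t_idx <- ((idx - 1L) %% nrow(trt)) + 1L  # cycle treatments within date
      data.frame(
        id = sprintf("%s-%02d", p$name, idx),
        species = p$name,
        svl_mm = stats::runif(n, p$svl_range_mm[1], p$svl_range_mm[2]),
        housing = sprintf("%s-H%d", p$name, ((idx - 1L) %% n_housing) + 1L),
        date = sprintf("d%02d", ((idx - 1L) %/% frogs_per_date) + 1L),
        water = trt$water[t_idx],
        temp_c = trt$temp_c[t_idx],
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Study-scale design
#'
#' The per-species sample sizes of the study: 32 X. tropicalis, 32
#' R. marina and 31 P. terribilis (95 animals), i.e. a balanced 8-per-cell
#' design with one P. terribilis removed from its last cell.
#'
#' @param seed Integer seed forwarded to [make_design()].
#' @return Design data frame with 95 rows.
#' @export
study_design <- function(seed = 1) {
  d <- make_design(8, seed = seed)
  drop_id <- utils::tail(d$id[d$species == "P.terribilis"], 1)
  d[d$id != drop_id, , drop = FALSE]
}

# Jittered measurement schedule: nominal grid plus uniform +/- jitter_min on
# every time after the first (weighings start exactly at treatment start).
measurement_times <- function(nominal = c(0, 20, 40, 60), jitter_min = 3) {
  t <- nominal
  if (length(t) > 1 && jitter_min > 0) {
    t[-1] <- t[-1] + stats::runif(length(t) - 1, -jitter_min, jitter_min)
  }
  t
}

# Linear predictor for one individual across a time vector, under the
# canonical coding (temperature centred, ln SVL centred per species).
linear_predictor <- function(species, water, temp_c, times, svl_mm, truth,
                             coding = ewl_coding(),
                             profiles = species_profiles()) {
  ctr <- svl_centers(coding, species, profiles = profiles)
  svl_ln_c <- log(svl_mm) - ctr[[species]]
  temp <- temp_c - coding$temp_center
  vapply(times, function(tm) {
    sum(lp_row(species, water, temp, tm, svl_ln_c) * truth$beta)
  }, numeric(1))
}

#' Simulate one individual's mass series
#'
#' Ln mass at each time is the fixed-effect linear predictor (under the
#' canonical coding) plus the individual's random-effect draws plus a
#' residual vector with Gaussian-kernel temporal correlation. With all
#' variance components zero the trajectory is exactly the linear predictor.
#'
#' @param individual One-row design data frame (or equivalent list) with
#'   `id`, `species`, `svl_mm`, `water`, `temp_c`.
#' @param truth An [ewl_truth()] parameter table.
#' @param times Strictly increasing measurement times, first equal to 0.
#' @param seed Optional integer seed.
#' @param ranef Optional list of pre-drawn random effects with numeric
#'   entries `frog`, `housing`, `date`, `species` (their sum shifts ln
#'   mass). If `NULL`, each is drawn independently from its component
#'   variance; experiment-level simulation passes shared draws instead.
#' @param coding An [ewl_coding()].
#' @param profiles Species profiles used for SVL centring.
#' @param ref_lag Reference lag of the temporal kernel in minutes.
#' @return A [mass_series()].
#' @export
simulate_series <- function(individual, truth, times = c(0, 20, 40, 60),
                            seed = NULL, ranef = NULL,
                            coding = ewl_coding(),
                            profiles = species_profiles(), ref_lag = 20) {
  times <- as.numeric(times)
  if (length(times) < 1 || (length(times) > 1 && any(diff(times) <= 0))) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (times[1] != 0) stop("first measurement time must be 0", call. = FALSE)
  with_seed(seed, {
    if (is.null(ranef)) {
      v <- truth$variances
      ranef <- list(frog = stats::rnorm(1, 0, sqrt(v[["frog"]])),
                    housing = stats::rnorm(1, 0, sqrt(v[["housing"]])),
                    date = stats::rnorm(1, 0, sqrt(v[["date"]])),
                    species = stats::rnorm(1, 0, sqrt(v[["species"]])))
    }
    lp <- linear_predictor(individual$species, individual$water,
                           individual$temp_c, times, individual$svl_mm,
                           truth, coding, profiles)
    u <- ranef$frog + ranef$housing + ranef$date + ranef$species
    v_e <- truth$variances[["error"]]
    eps <- if (v_e > 0) {
      K <- outer(times, times,
                 function(a, b) temporal_correlation(abs(a - b), truth$rho,
                                                     ref_lag))
      rmvn1(rep(0, length(times)), v_e * K + diag(1e-10, length(times)))
    } else {
      rep(0, length(times))
    }
    mass_series(individual$id, times, exp(lp + u + eps))
  })
}

#' Simulate a full experiment
#'
#' Draws the four random-effect sources once for the whole experiment --
#' species effects jointly from the phylogenetic correlation, housing, date
#' and frog effects independently -- then simulates every individual's
#' series on a jittered 20-min schedule.
#'
#' @param design Design data frame from [make_design()].
#' @param truth An [ewl_truth()].
#' @param seed Integer seed.
#' @param times Nominal measurement grid (minutes, starting at 0).
#' @param jitter_min Uniform timing jitter applied to non-zero times.
#' @param phylo Species correlation matrix used for the joint species
#'   draws; defaults to the built-in synthetic tree sample. Species missing
#'   from it are an error.
#' @param coding,profiles,ref_lag As in [simulate_series()].
#' @return A list with class `ewl_experiment`: `design`, `series` (named
#'   list of [mass_series()]), `truth`, `ranef`.
#' @export
simulate_experiment <- function(design, truth, seed = 1,
                                times = c(0, 20, 40, 60), jitter_min = 3,
                                phylo = NULL, coding = ewl_coding(),
                                profiles = species_profiles(), ref_lag = 20) {
  if (is.null(phylo)) phylo <- default_phylo_correlation()
  sp <- unique(design$species)
  if (!all(sp %in% rownames(phylo))) {
    stop("species missing from the phylogenetic correlation: ",
         paste(setdiff(sp, rownames(phylo)), collapse = ", "), call. = FALSE)
  }
  v <- truth$variances
  with_seed(seed, {
    u_species <- if (v[["species"]] > 0) {
      rmvn1(rep(0, length(sp)),
            v[["species"]] * phylo[sp, sp, drop = FALSE] +
              diag(1e-10, length(sp)))
    } else rep(0, length(sp))
    names(u_species) <- sp
    hg <- unique(design$housing)
    u_housing <- stats::setNames(stats::rnorm(length(hg), 0,
                                              sqrt(v[["housing"]])), hg)
    dt <- unique(design$date)
    u_date <- stats::setNames(stats::rnorm(length(dt), 0,
                                           sqrt(v[["date"]])), dt)
    u_frog <- stats::setNames(stats::rnorm(nrow(design), 0,
                                           sqrt(v[["frog"]])), design$id)
    series <- lapply(seq_len(nrow(design)), function(i) {
      ind <- design[i, ]
      tms <- measurement_times(times, jitter_min)
      simulate_series(ind, truth, tms, seed = NULL,
                      ranef = list(frog = u_frog[[ind$id]],
                                   housing = u_housing[[ind$housing]],
                                   date = u_date[[ind$date]],
                                   species = u_species[[ind$species]]),
                      coding = coding, profiles = profiles, ref_lag = ref_lag)
    })
    names(series) <- design$id
    structure(list(design = design, series = series, truth = truth,
                   ranef = list(species = u_species, housing = u_housing,
                                date = u_date, frog = u_frog)),
              class = "ewl_experiment")
  })
}

#' @export
print.ewl_experiment <- function(x, ...) {
  cat(sprintf("<ewl_experiment> %d individuals, %d species, %d measurements\n",
              nrow(x$design), length(unique(x$design$species)),
              sum(vapply(x$series, nrow, integer(1)))))
  invisible(x)
}

#' Corrupt a simulated series with field artefacts
#'
#' Applies, in order: (1) a single excretion event -- with probability
#' `excretion_prob` one measurement time (never the first) is chosen, a
#' fraction of the current mass in `excretion_frac_range` is recorded as
#' excreted, and that mass is subtracted from the chosen and all later
#' measurements; (2) dropout -- measurements taken after cumulative observed
#' loss exceeds `dropout_threshold` are flagged `truncated` and the series'
#' dropout flag is set; (3) sporadic missingness -- each interior
#' observation is masked (mass set to `NA`) with probability `missing_prob`.
#'
#' @param series A [mass_series()].
#' @param excretion_prob Per-individual probability of an excretion event.
#' @param excretion_frac_range Fraction of current body mass excreted,
#'   c(lo, hi) with 0 < lo < hi < 1.
#' @param missing_prob Per-observation masking probability (interior only).
#' @param dropout_threshold Fractional mass loss triggering removal (> 0).
#' @param seed Optional integer seed.
#' @param force_excretion Optional list(`index`, `frac`) forcing a specific
#'   event deterministically (used in tests and worked examples).
#' @return The corrupted [mass_series()].
#' @export
corrupt_series <- function(series, excretion_prob = 0.08,
                           excretion_frac_range = c(0.005, 0.03),
                           missing_prob = 0.02, dropout_threshold = 0.2,
                           seed = NULL, force_excretion = NULL) {
  stopifnot(excretion_prob >= 0, excretion_prob <= 1,
            missing_prob >= 0, missing_prob <= 1)
  lo <- excretion_frac_range[1]; hi <- excretion_frac_range[2]
  if (!(lo > 0 && lo < hi && hi < 1)) {
    stop("excretion_frac_range must satisfy 0 < lo < hi < 1", call. = FALSE)
  }
  if (dropout_threshold <= 0) {
    stop("dropout_threshold must be > 0", call. = FALSE)
  }
  df <- as.data.frame(series)
  n <- nrow(df)
  with_seed(seed, {
    # (1) excretion
    event <- NULL
    if (!is.null(force_excretion)) {
      event <- list(index = force_excretion$index, frac = force_excretion$frac)
    } else if (n > 1 && stats::runif(1) < excretion_prob) {
      event <- list(index = sample(2:n, 1), frac = stats::runif(1, lo, hi))
    }
    if (!is.null(event)) {
      e <- event$index
      w <- event$frac * df$mass_g[e]
      df$mass_g[e:n] <- df$mass_g[e:n] - w
      df$excreted_g[e] <- df$excreted_g[e] + w
    }
    # (2) dropout on observed (post-excretion) masses
    dropout <- FALSE
    if (n > 1) {
      loss <- 1 - df$mass_g / df$mass_g[1]
      gone <- which(loss > dropout_threshold)
      if (length(gone)) {
        df$status[gone] <- "truncated"
        dropout <- TRUE
      }
    }
    # (3) sporadic missingness at interior, non-truncated positions
    if (n > 2 && missing_prob > 0) {
      interior <- setdiff(2:(n - 1), which(df$status == "truncated"))
      hit <- interior[stats::runif(length(interior)) < missing_prob]
      df$status[hit] <- "masked"
      df$mass_g[hit] <- NA_real_
    }
    rebuild_series(df, series, dropout = dropout)
  })
}

#' Corrupt every series of an experiment
#'
#' Applies [corrupt_series()] to each individual. When `n_missing_total` is
#' given, per-series random masking is disabled and exactly that many
#' interior measurements, chosen uniformly across the whole experiment, are
#' masked instead (useful for bookkeeping checks with a known missing
#' count).
#'
#' @param experiment An `ewl_experiment`.
#' @param seed Integer seed.
#' @param n_missing_total Optional exact number of masked measurements.
#' @inheritParams corrupt_series
#' @return The experiment with corrupted series.
#' @export
corrupt_experiment <- function(experiment, excretion_prob = 0.08,
                               excretion_frac_range = c(0.005, 0.03),
                               missing_prob = 0.02, dropout_threshold = 0.2,
                               seed = 1, n_missing_total = NULL) {
  with_seed(seed, {
    per_series_missing <- if (is.null(n_missing_total)) missing_prob else 0
    experiment$series <- lapply(experiment$series, function(s) {
      corrupt_series(s, excretion_prob, excretion_frac_range,
                     per_series_missing, dropout_threshold, seed = NULL)
    })
    if (!is.null(n_missing_total)) {
      slots <- do.call(rbind, lapply(names(experiment$series), function(id) {
        s <- experiment$series[[id]]
        n <- nrow(s)
        ok <- if (n > 2) setdiff(2:(n - 1), which(s$status != "observed"))
              else integer(0)
        if (length(ok)) data.frame(id = id, row = ok) else NULL
      }))
      if (is.null(slots) || nrow(slots) < n_missing_total) {
        stop("not enough interior observations to mask", call. = FALSE)
      }
      pick <- slots[sample.int(nrow(slots), n_missing_total), , drop = FALSE]
      for (k in seq_len(nrow(pick))) {
        s <- experiment$series[[pick$id[k]]]
        df <- as.data.frame(s)
        df$status[pick$row[k]] <- "masked"
        df$mass_g[pick$row[k]] <- NA_real_
        experiment$series[[pick$id[k]]] <- rebuild_series(df, s)
      }
    }
    experiment
  })
}
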