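# Default run configuration; validate_config() rejects keys not listed
# here and type-checks overrides.
default_config <- function() {
  list(
    data = NULL, trees = NULL, output = NULL,
    preset = "table1",
    design = list(n_per_treatment = 8, study_scale = TRUE),
    times = c(0, 20, 40, 60), jitter_min = 3,
    temperatures = c(26, 36),
    corruption = list(enabled = TRUE, excretion_prob = 0.08,
                      excretion_frac_range = c(0.005, 0.03),
                      missing_prob = 0.02, dropout_threshold = 0.2),
    exclusion = list(max_loss_fraction = 0.2),
    coding = list(temp_center = 26, svl_center = "profile_midpoint"),
    priors = list(pilot_loss = -0.002, pilot_temp = -0.005),
    sampler = list(chains = 2, warmup = 300, samples = 300, L = 8,
                   target_accept = 0.8),
    mode = "nested",
    seeds = list(simulate = 1, corrupt = 2, fit = 3)
  )
}

merge_config <- function(defaults, user, path = character(0), log = NULL) {
  if (is.null(log)) log <- new.env()
  if (is.null(log$defaulted)) log$defaulted <- character(0)
  out <- defaults
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(paste(c(path, unknown[1]), collapse = "."), collapse = ", "),
         call. = FALSE)
  }
  for (k in names(defaults)) {
    if (k %in% names(user)) {
      if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
        out[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                 c(path, k), log)
      } else {
        out[[k]] <- if (is.null(user[[k]])) NULL else
          unlist(user[[k]], use.names = FALSE)
      }
    } else {
      log$defaulted <- c(log$defaulted, paste(c(path, k), collapse = "."))
    }
  }
  out
}

#' Validate and default a run configuration
#'
#' Parses a YAML file (or accepts a list), fills defaults, rejects unknown
#' keys and out-of-range values, and records which keys were defaulted.
#'
#' @param config Path to a YAML file, a YAML string, a list, or `NULL`
#'   (all defaults).
#' @return A list with class `ewl_config`; attribute `defaulted` lists the
#'   keys that fell back to defaults.
#' @export
validate_config <- function(config = NULL) {
  user <- if (is.null(config)) {
    list()
  } else if (is.character(config)) {
    parsed <- if (file.exists(config)) yaml::read_yaml(config)
              else yaml::yaml.load(config)
    if (is.null(parsed)) list() else parsed
  } else if (is.list(config)) {
    config
  } else {
    stop("config must be a path, YAML text, list or NULL", call. = FALSE)
  }
  log <- new.env()
  cfg <- merge_config(default_config(), user, log = log)

  s <- cfg$sampler
  if (s$chains < 1) stop("sampler.chains must be >= 1", call. = FALSE)
  if (s$warmup < 10 || s$samples < 10) {
    stop("sampler.warmup and sampler.samples must be >= 10", call. = FALSE)
  }
  if (!cfg$mode %in% c("nested", "composite")) {
    stop("mode must be 'nested' or 'composite'", call. = FALSE)
  }
  if (any(cfg$temperatures <= 0)) {
    stop("temperatures must be > 0", call. = FALSE)
  }
  co <- cfg$corruption
  if (co$excretion_prob < 0 || co$excretion_prob > 1 ||
      co$missing_prob < 0 || co$missing_prob > 1) {
    stop("corruption probabilities must lie in [0, 1]", call. = FALSE)
  }
  ex <- cfg$exclusion$max_loss_fraction
  if (ex <= 0 || ex >= 1) {
    stop("exclusion.max_loss_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!is.null(cfg$data) && !file.exists(cfg$data)) {
    stop("data file not found: ", cfg$data, call. = FALSE)
  }
  if (!is.null(cfg$trees) && !file.exists(cfg$trees)) {
    stop("tree file not found: ", cfg$trees, call. = FALSE)
  }
  structure(cfg, class = "ewl_config", defaulted = log$defaulted)
}

# Deterministic FNV-1a hash of the serialised configuration, for
# provenance stamping of output files. The output location is not part of
# the hash: the same analysis written to two directories is the same run.
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$output <- NULL
  txt <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                          null = "null")
  bytes <- utf8ToInt(as.character(txt))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(low, b)
    # multiply mod 2^32 in exact double arithmetic (split at 2^16)
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, preprocessing (excretion correction, imputation,
#' exclusions), covariance construction from the tree sample, HMC fitting
#' and posterior effect summaries, optionally writing every artefact to
#' `config$output` stamped with the configuration hash and seeds.
#'
#' @param config An `ewl_config` (or anything [validate_config()] accepts).
#' @return A list with class `ewl_run`: `frame`, `draws`, `summary`,
#'   `marginal_effects`, `variance_ratios`, `report`, `config`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- if (inherits(config, "ewl_config")) config else
    validate_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  experiment <- stage("simulate", {
    if (!is.null(cfg$data)) {
      read_experiment_csv(cfg$data)
    } else {
      truth <- truth_parameters(cfg$preset)
      design <- if (isTRUE(cfg$design$study_scale)) {
        study_design(seed = cfg$seeds$simulate)
      } else {
        make_design(cfg$design$n_per_treatment, seed = cfg$seeds$simulate,
                    temperatures = cfg$temperatures)
      }
      ex <- simulate_experiment(design, truth, seed = cfg$seeds$simulate,
                                times = cfg$times,
                                jitter_min = cfg$jitter_min)
      if (isTRUE(cfg$corruption$enabled)) {
        co <- cfg$corruption
        ex <- corrupt_experiment(ex, co$excretion_prob,
                                 co$excretion_frac_range, co$missing_prob,
                                 co$dropout_threshold,
                                 seed = cfg$seeds$corrupt)
      }
      ex
    }
  })

  prep <- stage("prep", {
    series <- lapply(experiment$series, function(s) {
      impute_series(correct_excretion(s))
    })
    miss <- missing_report(series)
    excl <- apply_exclusions(series,
                             cfg$exclusion$max_loss_fraction)
    coding <- ewl_coding(temp_center = cfg$coding$temp_center,
                         svl_center = cfg$coding$svl_center)
    frame <- build_model_frame(excl$retained, experiment$design, coding)
    list(frame = frame, missing = miss, exclusions = excl$report)
  })

  phylo <- stage("phylocov", {
    path <- cfg$trees %||% system.file("extdata",
                                       "synthetic_frog_trees.nwk",
                                       package = "ewlmm", mustWork = TRUE)
    phylo_correlation(mean_branch_tree(read_tree_sample(path)))
  })

  draws <- stage("fit", {
    priors <- default_priors(prep$frame, cfg$priors)
    s <- cfg$sampler
    fit_hmc(prep$frame, phylo, priors, chains = s$chains,
            warmup = s$warmup, samples = s$samples, seed = cfg$seeds$fit,
            mode = cfg$mode,
            control = list(L = s$L, target_accept = s$target_accept))
  })

  out <- stage("effects", {
    summ <- summarize_posterior(draws)
    eff <- marginal_effect_table(draws)
    vr <- list(
      species_housing = variance_ratio(summ, "species", "housing"),
      species_date = variance_ratio(summ, "species", "date"),
      species_frog = variance_ratio(summ, "species", "frog")
    )
    list(summary = summ, effects = eff, vr = vr)
  })

  report <- list(
    config_hash = config_hash(cfg),
    seeds = cfg$seeds,
    n_individuals = nrow(experiment$design),
    exclusions = prep$exclusions,
    missing = prep$missing,
    diagnostics = draws$diagnostics,
    divergences = draws$divergences,
    warnings = draws$warnings
  )

  if (!is.null(cfg$output)) {
    stage("write", write_run_outputs(cfg, experiment, prep, draws, out,
                                     report))
  }

  structure(
    list(frame = prep$frame, draws = draws, summary = out$summary,
         marginal_effects = out$effects, variance_ratios = out$vr,
         report = report, config = cfg),
    class = "ewl_run"
  )
}

write_run_outputs <- function(cfg, experiment, prep, draws, out, report) {
  dir.create(cfg$output, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config_hash: %s seed_fit: %d", report$config_hash,
                   cfg$seeds$fit)
  stamped_csv <- function(df, file) {
    path <- file.path(cfg$output, file)
    con <- file(path, "w")
    writeLines(stamp, con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  stamped_csv(as.data.frame(experiment), "data.csv")
  a <- draws$draws
  # long format: chain, iteration, parameter, value
  flat <- do.call(rbind, lapply(dimnames(a)[[3]], function(p) {
    do.call(rbind, lapply(seq_len(dim(a)[2]), function(ch) {
      data.frame(chain = ch, iteration = seq_len(dim(a)[1]), parameter = p,
                 value = a[, ch, p], stringsAsFactors = FALSE)
    }))
  }))
  stamped_csv(flat, "draws.csv")
  stamped_csv(out$summary, "summary.csv")
  stamped_csv(out$effects, "marginal_effects.csv")
  jsonlite::write_json(report, file.path(cfg$output, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(NULL)
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates an experiment from a known truth, fits the model,
#' and checks whether each true coefficient falls inside its 95% credible
#' interval. Simulation uses the clean generator (no corruption) so the
#' experiment isolates sampler and model correctness.
#'
#' @param n_reps Number of replicate simulations.
#' @param preset Truth preset (see [truth_parameters()]).
#' @param study_scale Use the 95-animal study design (else
#'   `n_per_treatment`).
#' @param n_per_treatment Cell size when `study_scale = FALSE`.
#' @param chains,warmup,samples,L Sampler geometry per replicate.
#' @param seed Integer seed; replicate r derives its seeds from it.
#' @param mode Covariance mode.
#' @return A list with class `ewl_recovery`: `coverage` (replicates x
#'   terms logical matrix), `estimates` (posterior means), `truth`,
#'   `coverage_rate`, `bias` (mean posterior-mean error per term).
#' @export
parameter_recovery <- function(n_reps = 20, preset = "table1",
                               study_scale = TRUE, n_per_treatment = 8,
                               chains = 2, warmup = 200, samples = 200,
                               L = 5, seed = 1, mode = "nested") {
  truth <- truth_parameters(preset)
  terms <- ewl_terms()
  phylo <- default_phylo_correlation()
  cover <- matrix(NA, n_reps, length(terms), dimnames = list(NULL, terms))
  est <- matrix(NA_real_, n_reps, length(terms),
                dimnames = list(NULL, terms))
  for (r in seq_len(n_reps)) {
    s <- seed + 1000L * r
    design <- if (study_scale) study_design(seed = s)
              else make_design(n_per_treatment, seed = s)
    ex <- simulate_experiment(design, truth, seed = s + 1L, phylo = phylo)
    frame <- build_model_frame(ex$series, design)
    priors <- default_priors(frame)
    fit <- fit_hmc(frame, phylo, priors, chains = chains, warmup = warmup,
                   samples = samples, seed = s + 2L, mode = mode,
                   control = list(L = L))
    summ <- summarize_posterior(fit)
    i <- match(terms, summ$term)
    cover[r, ] <- summ$q2.5[i] <= truth$beta & truth$beta <= summ$q97.5[i]
    est[r, ] <- summ$mean[i]
  }
  structure(
    list(coverage = cover, estimates = est, truth = truth,
         coverage_rate = mean(cover),
         bias = colMeans(est) - truth$beta),
    class = "ewl_recovery"
  )
}

#' @export
print.ewl_recovery <- function(x, ...) {
  cat(sprintf(
    "<ewl_recovery> %d replicates; CI coverage %.1f%%; |bias(Time)| = %.2e\n",
    nrow(x$coverage), 100 * x$coverage_rate, abs(x$bias[["Time"]])))
  invisible(x)
}

#' @export
print.ewl_run <- function(x, ...) {
  cat(sprintf(
    "<ewl_run> %d observations, %d excluded individuals, %.2f%% missing\n",
    nrow(x$frame), nrow(x$report$exclusions), x$report$missing$percent))
  cat(sprintf("  config %s; %d divergences; max R-hat %.3f\n",
              x$report$config_hash, x$report$divergences,
              max(x$report$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}
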