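#' Fit the hierarchical model by Hamiltonian Monte Carlo
#'
#' Samples the 19 fixed effects, the five variance components (log scale)
#' and the temporal correlation (logit scale) from the posterior defined by
#' [log_posterior()], using adaptive HMC with analytic gradients computed
#' against the marginalised covariance. When `fixed` supplies both the
#' variance components and `rho`, the covariance is precomputed once and
#' only the coefficients are sampled (the conjugate-reducible setting used
#' to validate the sampler against [gls_fit()]).
#'
#' @param frame An `ewl_model_frame`.
#' @param phylo Species correlation matrix.
#' @param priors An `ewl_priors`, or `NULL` for flat priors on the sampled
#'   coefficients (only allowed with `fixed` covariance).
#' @param chains,warmup,samples Sampler geometry. The study-scale settings
#'   (4 chains, 30000 warmup, 50000 samples) are available but desk-scale
#'   defaults are much smaller.
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param mode Covariance mode, `"nested"` or `"composite"`.
#' @param fixed Optional list(`variances`, `rho`) fixing the covariance.
#' @param control List: `L` (leapfrog steps, default 8), `target_accept`
#'   (0.8), `step0`, `nugget` (1e-8), `ref_lag` (20), `max_divergence_frac`
#'   (0.05; exceeding it only triggers a warning in the diagnostics).
#' @return An `ewl_draws` object: `draws` (iterations x chains x
#'   parameters), `diagnostics` (R-hat, ESS per parameter), `divergences`,
#'   `accept_rate`, `metadata`.
#' @export
fit_hmc <- function(frame, phylo, priors = NULL, chains = 4, warmup = 1000,
                    samples = 1000, seed = 1, mode = "nested",
                    fixed = NULL, control = list()) {
  if (nrow(frame) == 0) stop("empty model frame", call. = FALSE)
  L <- control$L %||% 8
  target <- control$target_accept %||% 0.8
  nugget <- control$nugget %||% 1e-8
  ref_lag <- control$ref_lag %||% 20
  X <- design_matrix(frame)
  y <- frame$ln_mass
  terms <- ewl_terms()
  vc <- ewl_variance_components()

  if (!is.null(fixed)) {
    if (is.null(fixed$variances) || is.null(fixed$rho)) {
      stop("fixed must supply both variances and rho", call. = FALSE)
    }
    sigma <- residual_covariance(frame, phylo,
                                 list(rho = fixed$rho, ref_lag = ref_lag),
                                 fixed$variances[vc], mode, nugget)
    R <- chol(sigma)
    Xt <- backsolve(R, X, transpose = TRUE)
    yt <- backsolve(R, y, transpose = TRUE)
    A <- crossprod(Xt)
    b <- drop(crossprod(Xt, yt))
    pm <- if (is.null(priors)) rep(0, 19) else priors$beta_mean[terms]
    pprec <- if (is.null(priors)) rep(0, 19) else 1 / priors$beta_sd[terms]^2
    lpg <- function(th) {
      g <- b - A %*% th - pprec * (th - pm)
      lp <- sum(th * b) - 0.5 * sum(th * (A %*% th)) -
        0.5 * sum(pprec * (th - pm)^2)
      list(lp = lp, grad = drop(g))
    }
    init_beta <- drop(chol2inv(chol(A + diag(pprec, 19))) %*%
                        (b + pprec * pm))
    sd_beta <- sqrt(diag(chol2inv(chol(A + diag(pprec + 1e-12, 19)))))
    mass0 <- pmax(diag(A) + pprec, 1e-12)
    par_names <- terms
    run_chain <- function(ch) {
      with_seed(seed + ch - 1, {
        init <- init_beta + stats::rnorm(19) * 0.25 * sd_beta
        hmc_chain(lpg, init, warmup, samples, L = L, target = target,
                  mass0 = mass0, step0 = control$step0 %||% 0.5)
      })
    }
  } else {
    if (is.null(priors)) {
      stop("priors are required when the covariance is sampled",
           call. = FALSE)
    }
    str <- covariance_structures(frame, phylo, mode, ref_lag)
    ptr <- ewl_model_build(X, y, str$W, str$D2, str$S_frog, str$S_housing,
                           str$S_date, str$S_species, nugget)
    pm <- priors$beta_mean[terms]
    psd <- priors$beta_sd[terms]
    a_v <- priors$variance_shape[vc]
    b_v <- priors$variance_scale[vc]
    # theta layout: beta (19), log variances (5), logit rho (1)
    lpg <- function(th) {
      beta <- th[1:19]
      lv <- th[20:24]
      v <- exp(lv)
      lr <- th[25]
      rho <- 1 / (1 + exp(-lr))
      if (any(!is.finite(v)) || rho <= 0 || rho >= 1) {
        return(list(lp = -Inf, grad = rep(NA_real_, 25)))
      }
      cc <- ewl_model_lpgrad(ptr, beta, v, rho)
      if (!isTRUE(cc$ok)) return(list(lp = -Inf, grad = rep(NA_real_, 25)))
      lp <- cc$ll +
        sum(stats::dnorm(beta, pm, psd, log = TRUE)) +
        sum(ldinvgamma(v, a_v, b_v)) +
        sum(lv) +                      # Jacobian of log transform
        log(rho) + log(1 - rho)        # Jacobian of logit transform
      g <- numeric(25)
      g[1:19] <- cc$gbeta - (beta - pm) / psd^2
      g[20:24] <- v * cc$gv + (-a_v + b_v / v)  # includes Jacobian term
      g[25] <- rho * (1 - rho) * cc$grho + (1 - 2 * rho)
      list(lp = lp, grad = g)
    }
    v0 <- c(frog = 0.05, housing = 0.1, date = 0.1, species = 1,
            error = 0.02)
    sigma0 <- residual_covariance(frame, phylo,
                                  list(rho = 0.5, ref_lag = ref_lag),
                                  v0, mode, nugget)
    g0 <- gls_fit(frame, sigma0, X)
    sd_beta <- sqrt(diag(g0$vcov))
    mass0 <- c(pmax(1 / sd_beta^2, 1e-12), rep(2, 5), 2)
    par_names <- c(terms, vc, "rho")
    run_chain <- function(ch) {
      with_seed(seed + ch - 1, {
        init <- c(g0$coefficients + stats::rnorm(19) * 0.25 * sd_beta,
                  log(v0) + stats::rnorm(5, 0, 0.3),
                  stats::qlogis(0.5) + stats::rnorm(1, 0, 0.3))
        hmc_chain(lpg, init, warmup, samples, L = L, target = target,
                  mass0 = mass0, step0 = control$step0 %||% 0.1)
      })
    }
  }

  res <- lapply(seq_len(chains), run_chain)
  draws <- array(NA_real_, c(samples, chains, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (ch in seq_len(chains)) {
    d <- res[[ch]]$draws
    if (!is.null(fixed)) {
      draws[, ch, ] <- d
    } else {
      d[, 20:24] <- exp(d[, 20:24])
      d[, 25] <- stats::plogis(d[, 25])
      draws[, ch, ] <- d
    }
  }
  diagnostics <- data.frame(
    parameter = par_names,
    rhat = vapply(par_names, function(p) split_rhat(draws[, , p]),
                  numeric(1)),
    ess = vapply(par_names, function(p) ess_mean(draws[, , p]), numeric(1)),
    row.names = NULL
  )
  n_div <- sum(vapply(res, function(r) r$divergences, numeric(1)))
  div_frac <- n_div / (chains * samples)
  max_div <- control$max_divergence_frac %||% 0.05
  structure(
    list(draws = draws, diagnostics = diagnostics, divergences = n_div,
         accept_rate = mean(vapply(res, function(r) r$accept_rate,
                                   numeric(1))),
         warnings = if (div_frac > max_div) {
           sprintf("divergence fraction %.3f exceeds %.3f", div_frac,
                   max_div)
         } else character(0),
         metadata = list(seed = seed, mode = mode, chains = chains,
                         warmup = warmup, samples = samples,
                         fixed = !is.null(fixed), ref_lag = ref_lag,
                         coding = attr(frame, "coding"))),
    class = "ewl_draws"
  )
}

#' @export
print.ewl_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf(
    "<ewl_draws> %d parameters, %d chains x %d samples; max R-hat %.3f, %d divergences\n",
    d[3], d[2], d[1], max(x$diagnostics$rhat, na.rm = TRUE),
    x$divergences))
  if (length(x$warnings)) cat("warning:", x$warnings, "\n")
  invisible(x)
}

#' Posterior summary table
#'
#' Per parameter: posterior mean, central 95% credible interval (2.5% and
#' 97.5% quantiles) and whether the interval excludes zero, ordered as the
#' canonical coefficient table (fixed effects, then variance components,
#' then `rho`).
#'
#' @param draws An `ewl_draws`, or a named list/matrix of draws.
#' @return Data frame with columns `term`, `mean`, `q2.5`, `q97.5`,
#'   `excludes_zero`.
#' @export
summarize_posterior <- function(draws) {
  mat <- draws_matrix(draws)
  qs <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- data.frame(term = colnames(mat), mean = colMeans(mat),
                    q2.5 = qs[1, ], q97.5 = qs[2, ],
                    stringsAsFactors = FALSE, row.names = NULL)
  out$excludes_zero <- out$q2.5 > 0 | out$q97.5 < 0
  out
}

# Flatten draws to an (iterations*chains) x parameters matrix.
draws_matrix <- function(draws) {
  if (inherits(draws, "ewl_draws")) {
    a <- draws$draws
    mat <- matrix(a, prod(dim(a)[1:2]), dim(a)[3])
    colnames(mat) <- dimnames(a)[[3]]
    return(mat)
  }
  if (is.matrix(draws)) return(draws)
  if (is.list(draws)) {
    return(do.call(cbind, draws))
  }
  stop("cannot interpret draws", call. = FALSE)
}

# Per-parameter draws as a vector.
param_draws <- function(draws, name) {
  mat <- draws_matrix(draws)
  if (!name %in% colnames(mat)) {
    stop("unknown parameter: ", name, call. = FALSE)
  }
  mat[, name]
}
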