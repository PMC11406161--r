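#' Fixed-effect design matrix
#'
#' Expands a model frame into the canonical 19-column design: intercept,
#' time, water, centred temperature, centred ln SVL, species dummies with
#' the X. tropicalis baseline, and all water/temperature/time/species
#' interaction products, in the order of [ewl_terms()].
#'
#' @param frame An `ewl_model_frame`.
#' @return Numeric matrix with 19 named columns.
#' @export
design_matrix <- function(frame) {
  bad <- setdiff(unique(frame$species), ewl_species_levels())
  if (length(bad)) {
    stop("unknown species label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  X <- t(vapply(seq_len(nrow(frame)), function(i) {
    lp_row(frame$species[i], frame$water[i], frame$temp[i],
           frame$time_min[i], frame$svl_ln_c[i])
  }, numeric(19)))
  colnames(X) <- ewl_terms()
  X
}

#' Default prior specification
#'
#' Normal priors on the fixed effects, inverse-gamma priors on the variance
#' components and a uniform(0,1) prior on the temporal correlation,
#' constructed from a small pilot configuration:
#' \itemize{
#'   \item the dehydration slope prior is centred at the pilot loss rate and
#'     the water uptake slope at minus twice that rate (uptake can be up to
#'     double dehydration);
#'   \item the water x temperature interaction prior assumes standing water
#'     shields a fraction of the body surface from evaporative heating --
#'     one half for the aquatic baseline species, one quarter for the two
#'     terrestrial species -- so its mean offsets the pilot temperature
#'     effect by those fractions;
#'   \item body-size information enters through the ln SVL range midpoint
#'     of each species (stored in `svl_midpoint_ln`);
#'   \item every normal sd is at least as large as the absolute prior mean
#'     (and never below a term-type floor), so zero always lies within two
#'     sd of the mean;
#'   \item the error variance gets a narrow inverse-gamma(3, 0.05) and each
#'     random-effect variance a wide inverse-gamma(2, 1).
#' }
#'
#' @param frame Model frame (used only to check species labels).
#' @param config List overriding `pilot_loss` (ln g/min), `pilot_temp`
#'   (ln g/degC), `cover_fraction` (named per species), `sd_floor_slope`,
#'   `sd_floor_level`, `invgamma_error`, `invgamma_group`.
#' @param profiles Species profiles supplying SVL ranges.
#' @return A list with class `ewl_priors`: `beta_mean`, `beta_sd` (named
#'   over [ewl_terms()]), `variance_shape`, `variance_scale` (named over
#'   components), `rho` = "uniform(0,1)", `svl_midpoint_ln`, `meta`.
#' @export
default_priors <- function(frame = NULL, config = list(),
                           profiles = species_profiles()) {
  pilot_loss <- config$pilot_loss %||% -0.002
  pilot_temp <- config$pilot_temp %||% -0.005
  cover <- config$cover_fraction %||%
    c(X.tropicalis = 0.5, R.marina = 0.25, P.terribilis = 0.25)
  floor_slope <- config$sd_floor_slope %||% 0.005
  floor_level <- config$sd_floor_level %||% 2
  ig_err <- config$invgamma_error %||% c(shape = 3, scale = 0.05)
  ig_grp <- config$invgamma_group %||% c(shape = 2, scale = 1)

  terms <- ewl_terms()
  mu <- stats::setNames(numeric(length(terms)), terms)
  mu["Time"] <- pilot_loss
  mu["Water-Time"] <- -2 * pilot_loss
  mu["Temp"] <- pilot_temp
  mu["Water-Temp"] <- -cover[["X.tropicalis"]] * pilot_temp
  mu["R.marina-Water-Temp"] <-
    (cover[["X.tropicalis"]] - cover[["R.marina"]]) * pilot_temp
  mu["P.terribilis-Water-Temp"] <-
    (cover[["X.tropicalis"]] - cover[["P.terribilis"]]) * pilot_temp

  slope_terms <- grepl("Time|Temp", terms)
  floor <- ifelse(slope_terms, floor_slope, floor_level)
  sd <- pmax(abs(mu), floor)

  svl_mid <- vapply(profiles, function(p) log(mean(p$svl_range_mm)),
                    numeric(1))
  names(svl_mid) <- vapply(profiles, function(p) p$name, character(1))

  vc <- ewl_variance_components()
  shape <- stats::setNames(rep(ig_grp[["shape"]], 5), vc)
  scale <- stats::setNames(rep(ig_grp[["scale"]], 5), vc)
  shape[["error"]] <- ig_err[["shape"]]
  scale[["error"]] <- ig_err[["scale"]]

  structure(
    list(beta_mean = mu, beta_sd = sd, variance_shape = shape,
         variance_scale = scale, rho = "uniform(0,1)",
         svl_midpoint_ln = svl_mid,
         meta = list(pilot_loss = pilot_loss, pilot_temp = pilot_temp,
                     uptake_factor = -2, cover_fraction = cover)),
    class = "ewl_priors"
  )
}

# Log prior (and its gradient pieces) on the natural scale.
log_prior <- function(beta, variances, rho, priors) {
  if (is.null(priors)) return(0)  # flat
  lp <- sum(stats::dnorm(beta, priors$beta_mean, priors$beta_sd, log = TRUE))
  lp <- lp + sum(ldinvgamma(variances, priors$variance_shape,
                            priors$variance_scale))
  lp  # rho ~ uniform(0,1): constant 0 inside the support
}

#' Log posterior density of the marginalised model
#'
#' Gaussian likelihood of ln mass with mean `X beta` and covariance built
#' by [residual_covariance()] (random effects marginalised analytically),
#' plus the log priors. Parameters outside the support return `-Inf`.
#'
#' @param theta Named list or vector with the 19 coefficients, the five
#'   variance components (named as in [ewl_variance_components()]) and
#'   `rho`.
#' @param frame An `ewl_model_frame`.
#' @param phylo Species correlation matrix.
#' @param priors An `ewl_priors`, or `NULL` for flat priors.
#' @param mode Covariance mode, `"nested"` or `"composite"`.
#' @param ref_lag Kernel reference lag in minutes.
#' @return Scalar log density.
#' @export
log_posterior <- function(theta, frame, phylo, priors = NULL,
                          mode = "nested", ref_lag = 20) {
  theta <- unlist(theta)
  beta <- theta[ewl_terms()]
  variances <- theta[ewl_variance_components()]
  rho <- theta[["rho"]]
  if (anyNA(beta) || anyNA(variances) || is.na(rho)) {
    stop("theta must name all 19 terms, 5 variances and rho", call. = FALSE)
  }
  if (any(variances <= 0) || rho <= 0 || rho >= 1) return(-Inf)
  sigma <- residual_covariance(frame, phylo, list(rho = rho,
                                                  ref_lag = ref_lag),
                               variances, mode)
  X <- design_matrix(frame)
  ll <- ldmvn(frame$ln_mass, drop(X %*% beta), sigma)
  ll + log_prior(beta, variances, rho, priors)
}

#' Generalised least squares oracle
#'
#' Exact GLS solution for a fixed observation covariance: the posterior
#' mode/mean under flat priors and known covariance. Used to validate the
#' sampler.
#'
#' @param frame An `ewl_model_frame` (or list with `ln_mass` and a design).
#' @param sigma Fixed positive-definite covariance matrix.
#' @param X Optional design matrix (defaults to [design_matrix()]).
#' @return List with `coefficients` (named), `vcov`, and `logdet` of sigma.
#' @export
gls_fit <- function(frame, sigma, X = NULL) {
  if (is.null(X)) X <- design_matrix(frame)
  y <- frame$ln_mass
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  R <- chol(sigma)
  Xt <- backsolve(R, X, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  A <- crossprod(Xt)
  b <- crossprod(Xt, yt)
  V <- chol2inv(chol(A))
  beta <- drop(V %*% b)
  names(beta) <- colnames(X)
  dimnames(V) <- list(colnames(X), colnames(X))
  list(coefficients = beta, vcov = V, logdet = 2 * sum(log(diag(R))))
}
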