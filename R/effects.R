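#' Posterior marginal effect of temperature
#'
#' The derivative of expected ln body mass with respect to temperature for
#' a given species and water condition is a linear contrast of the model
#' coefficients: `Temp`, plus the species-temperature contrast for
#' non-baseline species, plus -- in water -- `Water-Temp` and the
#' species-water-temperature contrast. The contrast is applied draw by
#' draw, so its posterior mean equals the contrast of the means.
#'
#' @param draws An `ewl_draws` (or matrix of draws over the 19 terms).
#' @param species Species label.
#' @param water Logical or 0/1 water condition.
#' @return A list with class `marginal_effect`: `species`, `water`,
#'   `draws`, `mean`, `q2.5`, `q97.5`, `p_negative`.
#' @export
marginal_temperature_effect <- function(draws, species, water) {
  if (!species %in% ewl_species_levels()) {
    stop("unknown species: ", species, call. = FALSE)
  }
  water <- as.integer(as.logical(water))
  eff <- param_draws(draws, "Temp")
  if (species != "X.tropicalis") {
    eff <- eff + param_draws(draws, paste0(species, "-Temp"))
  }
  if (water == 1L) {
    eff <- eff + param_draws(draws, "Water-Temp")
    if (species != "X.tropicalis") {
      eff <- eff + param_draws(draws, paste0(species, "-Water-Temp"))
    }
  }
  q <- stats::quantile(eff, c(0.025, 0.975), names = FALSE)
  structure(
    list(species = species, water = water, draws = eff, mean = mean(eff),
         q2.5 = q[1], q97.5 = q[2], p_negative = prob_direction(eff)),
    class = "marginal_effect"
  )
}

#' @export
print.marginal_effect <- function(x, ...) {
  cat(sprintf(
    "%s %s: %.4f ln g/degC [%.4f, %.4f], P(<0) = %.2f%%\n",
    x$species, if (x$water) "in water" else "not in water",
    x$mean, x$q2.5, x$q97.5, 100 * x$p_negative))
  invisible(x)
}

#' Posterior probability of a negative effect
#'
#' Fraction of draws strictly below zero; exact zeros count one half
#' (immaterial for continuous posteriors, stated for determinism).
#'
#' @param draws Numeric vector of effect draws (or a `marginal_effect`).
#' @return Probability in \[0, 1\].
#' @export
prob_direction <- function(draws) {
  if (inherits(draws, "marginal_effect")) draws <- draws$draws
  if (length(draws) < 1) stop("need at least one draw", call. = FALSE)
  (sum(draws < 0) + 0.5 * sum(draws == 0)) / length(draws)
}

#' Convert an ln-scale rate to percent change
#'
#' A coefficient `b` on the ln-mass scale corresponds to a
#' `100 * (exp(b) - 1)` percent change in mass per unit of the covariate.
#'
#' @param coefficient Ln-scale rate (e.g. ln g/min).
#' @return Percent change, sign preserved.
#' @export
percent_per_minute <- function(coefficient) {
  100 * (exp(coefficient) - 1)
}

#' Convert an ln-scale rate to absolute mass change
#'
#' @param coefficient Ln-scale rate (ln g/min).
#' @param reference_mass_g Reference body mass in g.
#' @return Mass change in mg per minute at the reference mass.
#' @export
mass_rate <- function(coefficient, reference_mass_g) {
  if (reference_mass_g <= 0) {
    stop("reference_mass_g must be > 0", call. = FALSE)
  }
  1000 * reference_mass_g * (exp(coefficient) - 1)
}

#' Ratio of posterior-mean variance components
#'
#' @param summary Posterior summary table from [summarize_posterior()] (or
#'   any data frame with `term` and `mean`).
#' @param numerator,denominator Term labels of the two variances.
#' @return List with `ratio` and `nearest_integer`.
#' @export
variance_ratio <- function(summary, numerator, denominator) {
  get_mean <- function(lbl) {
    i <- match(lbl, summary$term)
    if (is.na(i)) stop("term not found: ", lbl, call. = FALSE)
    summary$mean[i]
  }
  num <- get_mean(numerator)
  den <- get_mean(denominator)
  if (den == 0) stop("zero denominator variance", call. = FALSE)
  r <- num / den
  list(ratio = r, nearest_integer = round(r))
}

#' Classify a water x temperature outcome
#'
#' Assigns one of the qualitative outcome labels O1--O5 to a set of
#' per-condition net ln-mass slopes with credible intervals:
#' \itemize{
#'   \item O2 -- the in-water and no-water slope intervals at 26 degC
#'     overlap (no marginal water effect);
#'   \item O1 / O4 -- water matters but the 36 minus 26 degC slope contrast
#'     covers zero (no temperature interaction); O1 when the water slope is
#'     a gain, O4 when it is a loss;
#'   \item O3 / O5 -- a temperature interaction is present; O3 when the
#'     water slope is positive and the no-water interval is strictly
#'     negative, O5 when the water slope is non-positive;
#'   \item `"other"` when no rule applies.
#' }
#' When the 36 degC pair is absent the temperature contrast is treated as
#' covering zero. Contrast intervals are formed by a Gaussian combination
#' of the per-condition interval half-widths.
#'
#' @param slopes Data frame with columns `water` (0/1), `temp_c`, `mean`,
#'   `lo`, `hi`; must contain (water, 26) and (no-water, 26), optionally
#'   the 36 degC pair.
#' @return List with class `outcome_label`: `label` and `detail`.
#' @export
classify_outcome <- function(slopes) {
  need <- c("water", "temp_c", "mean", "lo", "hi")
  if (!all(need %in% names(slopes))) {
    stop("slopes must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(slopes$lo > slopes$hi)) {
    stop("interval bounds must be ordered lo <= hi", call. = FALSE)
  }
  pick <- function(w, tc) {
    i <- which(slopes$water == w & slopes$temp_c == tc)
    if (length(i) != 1) NULL else slopes[i, ]
  }
  w26 <- pick(1, 26); n26 <- pick(0, 26)
  if (is.null(w26) || is.null(n26)) {
    stop("slopes for (water, 26) and (no-water, 26) are required",
         call. = FALSE)
  }
  overlap <- w26$lo <= n26$hi && n26$lo <= w26$hi
  if (overlap) {
    return(structure(list(label = "O2",
                          detail = "26 degC slope intervals overlap"),
                     class = "outcome_label"))
  }
  contrast_covers_zero <- function(c26, c36) {
    if (is.null(c36)) return(TRUE)
    d <- c36$mean - c26$mean
    hw <- sqrt(((c26$hi - c26$lo) / 2)^2 + ((c36$hi - c36$lo) / 2)^2)
    (d - hw) <= 0 && 0 <= (d + hw)
  }
  no_interaction <- contrast_covers_zero(w26, pick(1, 36)) &&
    contrast_covers_zero(n26, pick(0, 36))
  if (no_interaction) {
    label <- if (w26$mean > 0) "O1" else "O4"
    return(structure(list(label = label,
                          detail = "no temperature interaction"),
                     class = "outcome_label"))
  }
  if (w26$mean > 0 && n26$hi < 0) {
    return(structure(list(label = "O3",
                          detail = "gain in water, strong loss without"),
                     class = "outcome_label"))
  }
  if (w26$mean <= 0) {
    return(structure(list(label = "O5",
                          detail = "net loss even in water"),
                     class = "outcome_label"))
  }
  structure(list(label = "other", detail = "rules conflict"),
            class = "outcome_label")
}

#' @export
print.outcome_label <- function(x, ...) {
  cat(sprintf("outcome %s (%s)\n", x$label, x$detail))
  invisible(x)
}

#' Marginal-effect table across species and water conditions
#'
#' Convenience wrapper producing the standard six-row table (three species
#' by two water conditions).
#'
#' @param draws An `ewl_draws`.
#' @return Data frame with `species`, `water`, `mean`, `q2.5`, `q97.5`,
#'   `p_negative`.
#' @export
marginal_effect_table <- function(draws) {
  grid <- expand.grid(species = ewl_species_levels(), water = c(1L, 0L),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    e <- marginal_temperature_effect(draws, grid$species[i], grid$water[i])
    data.frame(species = e$species, water = e$water, mean = e$mean,
               q2.5 = e$q2.5, q97.5 = e$q97.5, p_negative = e$p_negative,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
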