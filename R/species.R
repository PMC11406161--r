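#' Species profile
#'
#' Bundles the per-species constants the synthetic generator needs: a
#' plausible snout--vent length (SVL) range, a typical starting mass, and
#' the species' true ln-scale rates (dehydration slope out of water, added
#' uptake slope in water, and temperature effect per degC).
#'
#' @param name Species label, e.g. `"X.tropicalis"`.
#' @param svl_range_mm Length-2 numeric, min and max SVL in mm.
#' @param baseline_mass_g Typical starting mass in g.
#' @param loss_rate Ln-scale mass slope out of water (ln g/min), must be <= 0.
#' @param uptake_rate Added ln-scale slope when in water (ln g/min), >= 0.
#' @param temp_slope Ln-scale temperature effect (ln g/degC).
#' @return A list with class `species_profile`.
#' @export
species_profile <- function(name, svl_range_mm, baseline_mass_g,
                            loss_rate, uptake_rate, temp_slope) {
  stopifnot(length(svl_range_mm) == 2)
  if (!(svl_range_mm[1] > 0 && svl_range_mm[1] < svl_range_mm[2])) {
    stop("svl_range_mm must satisfy 0 < min < max", call. = FALSE)
  }
  if (baseline_mass_g <= 0) stop("baseline_mass_g must be > 0", call. = FALSE)
  if (loss_rate > 0) stop("loss_rate must be <= 0", call. = FALSE)
  if (uptake_rate < 0) stop("uptake_rate must be >= 0", call. = FALSE)
  structure(
    list(name = name, svl_range_mm = as.numeric(svl_range_mm),
         baseline_mass_g = baseline_mass_g, loss_rate = loss_rate,
         uptake_rate = uptake_rate, temp_slope = temp_slope),
    class = "species_profile"
  )
}

#' Default species profiles
#'
#' Profiles for the three study species: the aquatic Xenopus tropicalis
#' (small, fast water exchange), the terrestrial cane toad Rhinella marina
#' (large, high skin resistance, negligible net uptake over an hour), and the
#' terrestrial poison frog Phyllobates terribilis. Rates are per-species sums
#' of the model's posterior-mean slope terms; SVL ranges reflect adult sizes.
#'
#' @return Named list of [species_profile()] objects in the canonical
#'   species order (baseline first).
#' @export
species_profiles <- function() {
  list(
    X.tropicalis = species_profile(
      "X.tropicalis", svl_range_mm = c(28, 40), baseline_mass_g = 13.5,
      loss_rate = -0.0019, uptake_rate = 0.0023, temp_slope = -0.0092),
    R.marina = species_profile(
      "R.marina", svl_range_mm = c(85, 225), baseline_mass_g = 165,
      loss_rate = -0.0002, uptake_rate = 0, temp_slope = -0.0149),
    P.terribilis = species_profile(
      "P.terribilis", svl_range_mm = c(40, 52), baseline_mass_g = 5,
      loss_rate = -0.0021, uptake_rate = 0.0024, temp_slope = -0.0184)
  )
}

#' Experimental treatment
#'
#' One cell of the 2x2 design: standing water present or absent, incubation
#' temperature in degC (the study used 26 and 36).
#'
#' @param water_present Logical or 0/1 flag.
#' @param temperature_c Incubation temperature in degC, > 0.
#' @return A list with class `ewl_treatment`.
#' @export
treatment <- function(water_present, temperature_c) {
  if (!is.finite(temperature_c) || temperature_c <= 0) {
    stop("temperature_c must be > 0", call. = FALSE)
  }
  structure(list(water_present = as.integer(as.logical(water_present)),
                 temperature_c = temperature_c),
            class = "ewl_treatment")
}

# The four default treatments (water absence baseline, 26 then 36 degC).
default_treatments <- function(temperatures = c(26, 36)) {
  out <- list()
  for (w in c(0L, 1L)) for (tc in temperatures) {
    out[[length(out) + 1L]] <- treatment(w, tc)
  }
  out
}
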