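#' Fixed-effect terms of the water-loss model
#'
#' The hierarchical model regresses ln body mass (g) on time (min), water
#' availability, temperature and ln snout--vent length, with all water x
#' temperature, water x time and species interactions. The 19 terms are kept
#' in a fixed canonical order so coefficient vectors, design matrices and
#' posterior draws always align.
#'
#' @return Character vector of the 19 term names, in canonical order.
#' @export
ewl_terms <- function() {
  c(
    "Intercept", "Time", "Water", "Temp", "SVL",
    "R.marina", "P.terribilis",
    "R.marina-Temp", "P.terribilis-Temp",
    "Water-Temp",
    "P.terribilis-Water", "R.marina-Water",
    "P.terribilis-Water-Temp", "R.marina-Water-Temp",
    "P.terribilis-Time", "R.marina-Time",
    "Water-Time",
    "P.terribilis-Water-Time", "R.marina-Water-Time"
  )
}

#' Variance-component names
#'
#' Random-effect variances for individual frog, housing group, measurement
#' date and species, plus the residual (error) variance, all on the ln-gram
#' squared scale.
#'
#' @return Character vector of the five component names.
#' @export
ewl_variance_components <- function() {
  c("frog", "housing", "date", "species", "error")
}

# Species labels; the first is the reference level of the dummy coding.
ewl_species_levels <- function() c("X.tropicalis", "R.marina", "P.terribilis")

#' Default study coding
#'
#' Covariate coding used by both the simulator and the model frame builder:
#' water is a 0/1 indicator with the no-water baseline, temperature enters
#' centred at 26 degC (so the intercept refers to the cooler treatment), time
#' is minutes from treatment start, and ln SVL is centred at a per-species
#' reference (by default the ln midpoint of the species' plausible SVL
#' range, so the coding does not depend on the realised sample).
#'
#' @param temp_center Temperature (degC) subtracted from the raw temperature.
#' @param svl_center Either `"profile_midpoint"` (default), `"species_mean"`
#'   (centre at the within-species mean ln SVL of the data), or a named
#'   numeric vector of ln-mm centres keyed by species.
#' @param species_baseline Reference species for the dummy coding.
#' @return A list with class `ewl_coding`.
#' @export
ewl_coding <- function(temp_center = 26, svl_center = "profile_midpoint",
                       species_baseline = "X.tropicalis") {
  if (!identical(species_baseline, "X.tropicalis")) {
    stop("only the X.tropicalis baseline coding is implemented", call. = FALSE)
  }
  structure(
    list(temp_center = temp_center, svl_center = svl_center,
         species_baseline = species_baseline),
    class = "ewl_coding"
  )
}

# Resolve the per-species ln-SVL centre for a given coding.
# `svl_ln` / `species` supply data when svl_center == "species_mean".
svl_centers <- function(coding, species_present,
                        svl_ln = NULL, species = NULL,
                        profiles = species_profiles()) {
  sc <- coding$svl_center
  if (is.numeric(sc)) {
    missing <- setdiff(species_present, names(sc))
    if (length(missing)) {
      stop("no ln SVL centre supplied for species: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(sc[species_present])
  }
  if (identical(sc, "species_mean")) {
    if (is.null(svl_ln) || is.null(species)) {
      stop("species_mean centring needs observed SVL data", call. = FALSE)
    }
    out <- vapply(species_present,
                  function(s) mean(svl_ln[species == s]), numeric(1))
    return(out)
  }
  if (identical(sc, "profile_midpoint")) {
    prof_names <- vapply(profiles, function(p) p$name, character(1))
    out <- vapply(species_present, function(s) {
      i <- match(s, prof_names)
      if (is.na(i)) stop("no species profile for ", s, call. = FALSE)
      log(mean(profiles[[i]]$svl_range_mm))
    }, numeric(1))
    return(out)
  }
  stop("unknown svl_center: ", format(sc), call. = FALSE)
}

# Single design-matrix row on the canonical 19-term coding.
# temp and svl_ln_c are already centred; water is 0/1; time in minutes.
lp_row <- function(species, water, temp, time, svl_ln_c) {
  rm <- as.numeric(species == "R.marina")
  pt <- as.numeric(species == "P.terribilis")
  c(
    1, time, water, temp, svl_ln_c,
    rm, pt,
    rm * temp, pt * temp,
    water * temp,
    pt * water, rm * water,
    pt * water * temp, rm * water * temp,
    pt * time, rm * time,
    water * time,
    pt * water * time, rm * water * time
  )
}
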