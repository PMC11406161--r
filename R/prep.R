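#' Correct masses for urination/defecation events
#'
#' Mass lost by excretion is not evaporative, so each recorded excreted
#' mass `w` at time `t*` is added back to the measurement at `t*` and every
#' later one (cumulatively across multiple events). First differences away
#' from event times are unchanged.
#'
#' @param series A [mass_series()] with `excreted_g` recorded at event times.
#' @return The corrected [mass_series()]; provenance status is preserved.
#' @export
correct_excretion <- function(series) {
  if (any(series$excreted_g < 0, na.rm = TRUE)) {
    stop("excreted mass must be >= 0", call. = FALSE)
  }
  df <- as.data.frame(series)
  df$mass_g <- df$mass_g + cumsum(df$excreted_g)
  rebuild_series(df, series)
}

#' Impute masked measurements
#'
#' Two rules: `"regression"` predicts each masked mass from a linear
#' regression of mass on time over all available (non-masked) measurements
#' of the individual; `"adjacent"` fills a masked value with the mean of
#' its immediately neighbouring available measurements. Observed values are
#' never altered.
#'
#' @param series A [mass_series()].
#' @param mode `"regression"` or `"adjacent"`.
#' @return The series with masked entries filled and status set to
#'   `imputed_regression` / `imputed_adjacent`.
#' @export
impute_missing <- function(series, mode = c("regression", "adjacent")) {
  mode <- match.arg(mode)
  df <- as.data.frame(series)
  gaps <- which(df$status == "masked")
  if (length(gaps) == 0) return(series)
  avail <- which(!is.na(df$mass_g))
  if (mode == "regression") {
    if (length(avail) < 2) {
      stop("regression imputation needs >= 2 available measurements",
           call. = FALSE)
    }
    fit <- stats::lm(mass_g ~ time_min, data = df[avail, ])
    df$mass_g[gaps] <- stats::predict(fit,
                                      newdata = df[gaps, , drop = FALSE])
    df$status[gaps] <- "imputed_regression"
  } else {
    for (g in gaps) {
      if (g == 1L || g == nrow(df) ||
          is.na(df$mass_g[g - 1L]) || is.na(df$mass_g[g + 1L])) {
        stop("adjacent imputation needs an available neighbour on each side",
             call. = FALSE)
      }
      df$mass_g[g] <- (df$mass_g[g - 1L] + df$mass_g[g + 1L]) / 2
      df$status[g] <- "imputed_adjacent"
    }
  }
  rebuild_series(df, series)
}

#' Default imputation policy
#'
#' Interior single gaps with a measured value on each side are filled by
#' the adjacent-mean rule (the situation arising when a weighing window
#' overlaps another animal's endpoint); every other gap falls back to
#' per-individual regression imputation.
#'
#' @param series A [mass_series()].
#' @return The imputed series.
#' @export
impute_series <- function(series) {
  df <- as.data.frame(series)
  gaps <- which(df$status == "masked")
  if (length(gaps) == 0) return(series)
  adjacent_ok <- vapply(gaps, function(g) {
    g > 1L && g < nrow(df) &&
      !is.na(df$mass_g[g - 1L]) && !is.na(df$mass_g[g + 1L])
  }, logical(1))
  for (g in gaps[adjacent_ok]) {
    df$mass_g[g] <- (df$mass_g[g - 1L] + df$mass_g[g + 1L]) / 2
    df$status[g] <- "imputed_adjacent"
  }
  out <- rebuild_series(df, series)
  if (any(!adjacent_ok)) out <- impute_missing(out, "regression")
  out
}

#' Apply the study's exclusion rules
#'
#' Removes individuals whose corrected trajectory loses more than
#' `max_loss_fraction` of the starting mass (the study's 20% rule) or that
#' carry a manual exclusion flag (e.g. no righting response), and reports
#' each exclusion with its reason.
#'
#' @param series_set List of [mass_series()].
#' @param max_loss_fraction Fractional loss threshold in (0, 1).
#' @param manual_ids Ids to exclude regardless of mass loss.
#' @return A list: `retained` (list of series) and `report` (data frame
#'   with `id`, `reason`, `loss_fraction`).
#' @export
apply_exclusions <- function(series_set, max_loss_fraction = 0.2,
                             manual_ids = character(0)) {
  if (!(max_loss_fraction > 0 && max_loss_fraction < 1)) {
    stop("max_loss_fraction must lie in (0, 1)", call. = FALSE)
  }
  report <- data.frame(id = character(0), reason = character(0),
                       loss_fraction = numeric(0), stringsAsFactors = FALSE)
  keep <- logical(length(series_set))
  for (i in seq_along(series_set)) {
    s <- series_set[[i]]
    m <- s$mass_g[!is.na(s$mass_g)]
    loss <- if (length(m) > 1) max(1 - m / m[1]) else 0
    id <- series_id(s)
    if (id %in% manual_ids) {
      report <- rbind(report, data.frame(id = id, reason = "manual",
                                         loss_fraction = loss))
    } else if (loss > max_loss_fraction) {
      report <- rbind(report, data.frame(id = id, reason = "mass_loss",
                                         loss_fraction = loss))
    } else {
      keep[i] <- TRUE
    }
  }
  retained <- series_set[keep]
  names(retained) <- vapply(retained, series_id, character(1))
  list(retained = retained, report = report)
}

#' Missing-measurement bookkeeping
#'
#' Counts measurements that were scheduled but not directly observed
#' (masked, or already imputed) against all scheduled measurements, before
#' any exclusion.
#'
#' @param x An `ewl_experiment` or list of [mass_series()].
#' @return List with `n_missing`, `n_total` and `percent` (0--100).
#' @export
missing_report <- function(x) {
  series <- if (inherits(x, "ewl_experiment")) x$series else x
  st <- unlist(lapply(series, function(s) s$status))
  n_missing <- sum(st %in% c("masked", "imputed_regression",
                             "imputed_adjacent"))
  n_total <- length(st)
  list(n_missing = n_missing, n_total = n_total,
       percent = 100 * n_missing / n_total)
}

#' Build the coded regression table
#'
#' Joins each retained series with its design row and produces one row per
#' usable measurement, with the response `ln_mass` (ln g) and covariates
#' coded per `coding`: `time_min` (min), `water` (0/1, no-water baseline),
#' `temp` (degC centred), `svl_ln_c` (ln mm, centred per species), plus the
#' grouping labels. Truncated measurements are dropped; masked measurements
#' must have been imputed first. Rows are ordered by individual (design
#' order) then time.
#'
#' @param series_set List of [mass_series()].
#' @param design Design data frame (one row per individual).
#' @param coding An [ewl_coding()].
#' @param profiles Species profiles (for midpoint SVL centring).
#' @return Data frame with class `ewl_model_frame`; the coding and the ln
#'   SVL centres used are attached as attributes.
#' @export
build_model_frame <- function(series_set, design, coding = ewl_coding(),
                              profiles = species_profiles()) {
  ids <- vapply(series_set, series_id, character(1))
  unmatched <- setdiff(ids, design$id)
  if (length(unmatched)) {
    stop("no design row for individual(s): ",
         paste(unmatched, collapse = ", "), call. = FALSE)
  }
  ord <- order(match(ids, design$id))
  rows <- lapply(series_set[ord], function(s) {
    d <- design[design$id == series_id(s), ]
    df <- as.data.frame(s)
    df <- df[df$status != "truncated", , drop = FALSE]
    if (any(df$status == "masked")) {
      stop("individual ", series_id(s),
           " has unimputed masked measurements", call. = FALSE)
    }
    if (any(df$mass_g <= 0)) {
      stop("nonpositive mass for individual ", series_id(s), call. = FALSE)
    }
    data.frame(id = d$id, species = d$species, housing = d$housing,
               date = d$date, water = d$water, temp_c = d$temp_c,
               svl_mm = d$svl_mm, time_min = df$time_min,
               mass_g = df$mass_g, ln_mass = log(df$mass_g),
               status = df$status, stringsAsFactors = FALSE)
  })
  frame <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  sp <- unique(frame$species)
  centers <- svl_centers(coding, sp, svl_ln = log(frame$svl_mm),
                         species = frame$species, profiles = profiles)
  frame$svl_ln <- log(frame$svl_mm)
  frame$svl_ln_c <- frame$svl_ln - centers[frame$species]
  frame$temp <- frame$temp_c - coding$temp_center
  attr(frame, "coding") <- coding
  attr(frame, "svl_centers") <- centers
  class(frame) <- c("ewl_model_frame", "data.frame")
  frame
}
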