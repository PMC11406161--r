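#' One individual's timed body-mass series
#'
#' A small classed data frame holding the measurement times (minutes from
#' treatment start), masses (g), any recorded excreted mass (urine/stool, g,
#' attached to the time at which it was noticed), and a per-observation
#' provenance status.
#'
#' Status levels: `observed` (measured), `masked` (scheduled but not
#' measured; mass is `NA` until imputed), `imputed_regression` /
#' `imputed_adjacent` (filled by the two imputation rules), and `truncated`
#' (measurement discarded because the animal had already crossed the
#' dropout threshold).
#'
#' @param id Individual label.
#' @param time_min Strictly increasing times in minutes, first usually 0.
#' @param mass_g Masses in g; `NA` only where status is `masked`.
#' @param excreted_g Excreted mass recorded at each time (g, >= 0).
#' @param status Character vector of provenance flags.
#' @param dropout Logical: did the animal cross the dropout threshold?
#' @return A data frame with class `mass_series`.
#' @export
mass_series <- function(id, time_min, mass_g,
                        excreted_g = rep(0, length(time_min)),
                        status = rep("observed", length(time_min)),
                        dropout = FALSE) {
  n <- length(time_min)
  if (length(mass_g) != n || length(excreted_g) != n || length(status) != n) {
    stop("time_min, mass_g, excreted_g and status must have equal length",
         call. = FALSE)
  }
  if (n > 1 && any(diff(time_min) <= 0)) {
    stop("time_min must be strictly increasing", call. = FALSE)
  }
  ok_status <- c("observed", "masked", "imputed_regression",
                 "imputed_adjacent", "truncated")
  if (!all(status %in% ok_status)) {
    stop("unknown status value(s): ",
         paste(setdiff(status, ok_status), collapse = ", "), call. = FALSE)
  }
  bad_mass <- !is.na(mass_g) & mass_g <= 0
  if (any(bad_mass)) stop("masses must be strictly positive", call. = FALSE)
  if (any(is.na(mass_g) & status != "masked")) {
    stop("NA mass is only allowed at masked entries", call. = FALSE)
  }
  if (any(excreted_g < 0, na.rm = TRUE)) {
    stop("excreted_g must be >= 0", call. = FALSE)
  }
  out <- data.frame(time_min = as.numeric(time_min),
                    mass_g = as.numeric(mass_g),
                    excreted_g = as.numeric(excreted_g),
                    status = as.character(status),
                    stringsAsFactors = FALSE)
  attr(out, "id") <- as.character(id)
  attr(out, "dropout") <- isTRUE(dropout)
  class(out) <- c("mass_series", "data.frame")
  out
}

series_id <- function(series) attr(series, "id")

#' @export
print.mass_series <- function(x, ...) {
  cat(sprintf("<mass_series> %s (%d obs%s)\n", series_id(x), nrow(x),
              if (isTRUE(attr(x, "dropout"))) ", dropout" else ""))
  print(as.data.frame(x), ...)
  invisible(x)
}

# Rebuild a mass_series from a modified data frame, keeping attributes.
rebuild_series <- function(df, template, dropout = attr(template, "dropout")) {
  mass_series(series_id(template), df$time_min, df$mass_g, df$excreted_g,
              df$status, dropout = dropout)
}
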