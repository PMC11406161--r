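#' Write an experiment as long-format CSV
#'
#' One row per individual x time point with columns `id, species, housing,
#' date, water, temp_c, svl_mm, time_min, mass_g, excreted_g, observed,
#' dropout`. `observed` is 1 for directly measured masses (0 for masked or
#' imputed ones) and `dropout` flags measurements past the dropout
#' threshold.
#'
#' @param experiment An `ewl_experiment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_experiment_csv <- function(experiment, path) {
  utils::write.csv(as.data.frame(experiment), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
as.data.frame.ewl_experiment <- function(x, ...) {
  rows <- lapply(names(x$series), function(id) {
    s <- x$series[[id]]
    d <- x$design[x$design$id == id, ]
    data.frame(id = id, species = d$species, housing = d$housing,
               date = d$date, water = d$water, temp_c = d$temp_c,
               svl_mm = d$svl_mm, time_min = s$time_min, mass_g = s$mass_g,
               excreted_g = s$excreted_g,
               observed = as.integer(s$status == "observed"),
               dropout = as.integer(s$status == "truncated"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Read an experiment from long-format CSV
#'
#' Inverse of [write_experiment_csv()]. Rows with `observed == 0` and no
#' mass are restored as masked; rows with `dropout == 1` as truncated.
#' Externally deposited tables with different column names can be read by
#' supplying `column_map`; unmapped optional columns (`excreted_g`,
#' `observed`, `dropout`) default to no events / fully observed.
#'
#' @param path CSV path in the dialect written by [write_experiment_csv()].
#' @param column_map Optional named character vector mapping this
#'   package's column names to those found in the file, e.g.
#'   `c(svl_mm = "SVL", mass_g = "mass")`.
#' @return An `ewl_experiment` (without truth or random-effect entries).
#' @export
read_experiment_csv <- function(path, column_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (ours in names(column_map)) {
      theirs <- column_map[[ours]]
      if (!theirs %in% names(df)) {
        stop("mapped column not in file: ", theirs, call. = FALSE)
      }
      names(df)[names(df) == theirs] <- ours
    }
  }
  if (!"excreted_g" %in% names(df)) df$excreted_g <- 0
  if (!"observed" %in% names(df)) df$observed <- 1L
  if (!"dropout" %in% names(df)) df$dropout <- 0L
  need <- c("id", "species", "housing", "date", "water", "temp_c", "svl_mm",
            "time_min", "mass_g", "excreted_g", "observed", "dropout")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing columns in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(df$id)
  design <- df[!duplicated(df$id),
               c("id", "species", "svl_mm", "housing", "date", "water",
                 "temp_c")]
  rownames(design) <- NULL
  series <- lapply(ids, function(i) {
    d <- df[df$id == i, ]
    d <- d[order(d$time_min), ]
    status <- ifelse(d$dropout == 1, "truncated",
                     ifelse(d$observed == 1, "observed",
                            ifelse(is.na(d$mass_g), "masked",
                                   "imputed_regression")))
    mass_series(i, d$time_min, d$mass_g, d$excreted_g, status,
                dropout = any(d$dropout == 1))
  })
  names(series) <- ids
  structure(list(design = design, series = series, truth = NULL,
                 ranef = NULL), class = "ewl_experiment")
}

#' Write / read a truth table as JSON
#'
#' @param truth An [ewl_truth()].
#' @param path JSON path.
#' @return `path` invisibly, or the [ewl_truth()] read back.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(beta = as.list(truth$beta), variances = as.list(truth$variances),
         rho = truth$rho),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ewl_truth(unlist(x$beta), unlist(x$variances), x$rho)
}
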