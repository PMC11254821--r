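## Reading/writing sample and questionnaire tables, plus QA/QC recovery
## statistics.  Tables are plain data frames; one row per (sample,
## element) for concentrations, one row per respondent for the survey.

SAMPLE_COLUMNS <- c("sample_id", "origin", "element",
                    "total_conc", "gastric_conc", "intestinal_conc")
RESPONDENT_COLUMNS <- c("respondent_id", "sex", "exposure_frequency",
                        "body_weight")

#' Read a per-sample element concentration table
#'
#' Reads a CSV holding, per earthworm batch and element, the total
#' concentration and the gastric- and intestinal-phase soluble
#' concentrations (all mg/kg dry weight).  Rows with a missing
#' concentration are kept and flagged in the `incomplete` attribute, not
#' silently dropped; downstream aggregation excludes them explicitly.
#'
#' @param path CSV file path (comma-separated, UTF-8, `.` decimal).
#' @param schema Optional named character vector mapping the canonical
#'   column names (`sample_id`, `origin`, `element`, `total_conc`,
#'   `gastric_conc`, `intestinal_conc`) to the file's column names.
#' @return A `data.frame` with the canonical columns, one row per
#'   (sample, element); attribute `incomplete` holds the indices of rows
#'   with any missing concentration.
#' @seealso [write_samples()], [read_respondents()]
#' @export
read_samples <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  df <- remap_columns(raw, SAMPLE_COLUMNS, schema)
  num_cols <- c("total_conc", "gastric_conc", "intestinal_conc")
  for (col in num_cols) df[[col]] <- as.numeric(df[[col]])

  bad_el <- !is.na(df$element) & !(df$element %in% WORM_ELEMENTS)
  if (any(bad_el))
    stop("unknown element(s) in rows ",
         paste(which(bad_el), collapse = ", "), ": ",
         paste(unique(df$element[bad_el]), collapse = ", "))
  for (col in num_cols) {
    neg <- !is.na(df[[col]]) & df[[col]] < 0
    if (any(neg))
      stop("negative ", col, " in row(s) ",
           paste(which(neg), collapse = ", "))
  }

  incomplete <- which(!stats::complete.cases(df[num_cols]))
  if (length(incomplete))
    message(length(incomplete),
            " row(s) with missing concentrations flagged")
  structure(df, incomplete = incomplete)
}

#' Write a sample table to CSV
#'
#' @param samples Data frame as returned by [read_samples()] or
#'   [generate_samples()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  stopifnot(all(SAMPLE_COLUMNS %in% names(samples)))
  utils::write.csv(samples[SAMPLE_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a questionnaire (respondent) table
#'
#' Each row is one survey respondent: sex, exposure frequency to
#' earthworm preparations (days/year) and body weight (kg).
#'
#' @inheritParams read_samples
#' @return A `data.frame` with columns `respondent_id`, `sex`
#'   (`"male"`/`"female"`), `exposure_frequency`, `body_weight`.
#' @export
read_respondents <- function(path, schema = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  df <- remap_columns(raw, RESPONDENT_COLUMNS, schema)
  df$exposure_frequency <- as.numeric(df$exposure_frequency)
  df$body_weight <- as.numeric(df$body_weight)
  if (!all(df$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  ef <- df$exposure_frequency
  if (any(!is.na(ef) & (ef < 0 | ef > 365)))
    stop("exposure_frequency must lie in [0, 365] days/year")
  if (any(!is.na(df$body_weight) & df$body_weight <= 0))
    stop("body_weight must be positive")
  df
}

#' Write a respondent table to CSV
#' @inheritParams write_samples
#' @param respondents Data frame as returned by [read_respondents()].
#' @return `path`, invisibly.
#' @export
write_respondents <- function(respondents, path) {
  stopifnot(all(RESPONDENT_COLUMNS %in% names(respondents)))
  utils::write.csv(respondents[RESPONDENT_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

remap_columns <- function(df, canonical, schema) {
  if (!is.null(schema)) {
    stopifnot(is.character(schema), !is.null(names(schema)))
    for (canon in names(schema)) {
      src <- schema[[canon]]
      if (!src %in% names(df))
        stop("schema maps '", canon, "' to missing column '", src, "'")
      names(df)[names(df) == src] <- canon
    }
  }
  missing <- setdiff(canonical, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df[canonical]
}

#' Spike-recovery statistics for analytical QA/QC
#'
#' Mean and sample standard deviation of percent recovery
#' (`100 * measured / spiked`) across replicate spiked samples, the
#' standard accuracy control for ICP-MS element determination.
#'
#' @param measured Numeric vector of measured concentrations.
#' @param spiked Numeric vector of known spiked concentrations (> 0),
#'   same length as `measured`.
#' @param element Element label (one of [risk_elements()]).
#' @return A `recovery_stats` object (list with `element`,
#'   `mean_recovery`, `sd_recovery` in percent, and `n`).
#' @examples
#' recovery_stats(c(0.95, 1.01), c(1, 1), "Cd")  # 98% +/- 4.24%
#' @export
recovery_stats <- function(measured, spiked, element) {
  stopifnot(is.numeric(measured), is.numeric(spiked))
  if (length(measured) != length(spiked))
    stop("measured and spiked must have equal length")
  if (any(spiked <= 0)) stop("spiked values must be > 0")
  element <- match.arg(element, WORM_ELEMENTS)
  pct <- 100 * measured / spiked
  n <- length(pct)
  structure(list(element = element,
                 mean_recovery = mean(pct),
                 sd_recovery = if (n >= 2) stats::sd(pct) else NA_real_,
                 n = n),
            class = "recovery_stats")
}

#' @export
print.recovery_stats <- function(x, ...) {
  sd_txt <- if (is.na(x$sd_recovery)) "" else
    sprintf(" +/- %.2f%%", x$sd_recovery)
  cat(sprintf("Recovery %s: %.1f%%%s (n = %d)\n",
              x$element, x$mean_recovery, sd_txt, x$n))
  invisible(x)
}

#' Export recovery statistics as JSON
#'
#' @param stats A `recovery_stats` object or list of them.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_recovery_json <- function(stats, path) {
  if (inherits(stats, "recovery_stats")) stats <- list(stats)
  payload <- lapply(stats, function(s) {
    list(element = s$element, mean_recovery = s$mean_recovery,
         sd_recovery = s$sd_recovery, n = s$n)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
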