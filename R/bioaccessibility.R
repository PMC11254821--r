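## Bioaccessible content and bioaccessibility percent per sample, and
## Table-style aggregation by origin.
##
## Bioaccessibility % = 100 * (gastric + intestinal soluble content) /
## total content.  Values above 100% indicate measurement noise (the
## two-phase extraction recovering more than the independent total
## digestion); they are flagged, never silently truncated.

#' Per-sample bioaccessible content and bioaccessibility percent
#'
#' The bioaccessible content of an element is the sum of its soluble
#' concentrations in the simulated gastric and intestinal phases; the
#' bioaccessibility percent relates that sum to the total concentration
#' from full acid digestion.
#'
#' @param samples Data frame with columns `sample_id`, `origin`,
#'   `element`, `total_conc`, `gastric_conc`, `intestinal_conc`
#'   (see [read_samples()]).
#' @param cap_at_100 Cap bioaccessibility at 100% (default `FALSE`).
#'   Intended for risk runs where a >100% ratio would inflate doses;
#'   the default keeps QC problems visible.
#' @return Data frame with `sample_id`, `origin`, `element`,
#'   `bioaccessible_conc` (mg/kg), `bioaccessibility_pct` and a logical
#'   `flag_over_100`.  Rows whose total is missing get `NA` percent;
#'   a zero total is an error (undefined ratio).
#' @examples
#' s <- data.frame(sample_id = "s1", origin = "A", element = "Cd",
#'                 total_conc = 2, gastric_conc = 0.5,
#'                 intestinal_conc = 0.36)
#' bioaccessible_content(s)  # 0.86 mg/kg, 43%
#' @export
bioaccessible_content <- function(samples, cap_at_100 = FALSE) {
  needed <- c("sample_id", "origin", "element", "total_conc",
              "gastric_conc", "intestinal_conc")
  stopifnot(all(needed %in% names(samples)))
  tot <- samples$total_conc
  if (any(!is.na(tot) & tot == 0))
    stop("total_conc of 0 makes bioaccessibility undefined (row(s) ",
         paste(which(!is.na(tot) & tot == 0), collapse = ", "), ")")
  bio <- samples$gastric_conc + samples$intestinal_conc
  pct <- 100 * bio / tot
  over <- !is.na(pct) & pct > 100
  if (cap_at_100) pct <- pmin(pct, 100)
  out <- data.frame(sample_id = samples$sample_id,
                    origin = samples$origin,
                    element = samples$element,
                    bioaccessible_conc = bio,
                    bioaccessibility_pct = pct,
                    flag_over_100 = over,
                    stringsAsFactors = FALSE)
  if (any(over))
    message(sum(over), " sample(s) with bioaccessibility > 100% flagged")
  out
}

#' Summarise bioaccessible concentrations by origin
#'
#' Mean and sample SD (n - 1 denominator) of the bioaccessible
#' concentration per (origin, element), mirroring the conventional
#' "Mean +/- SD" origin table.  Origins contributing a single batch
#' report the mean only (`sd_conc = NA`).
#'
#' @param results Output of [bioaccessible_content()].
#' @return Data frame `origin`, `element`, `n_batches`, `mean_conc`,
#'   `sd_conc`, ordered by origin then element.
#' @export
summarize_by_origin <- function(results) {
  stopifnot(all(c("origin", "element", "bioaccessible_conc") %in%
                  names(results)))
  ok <- !is.na(results$bioaccessible_conc)
  dropped <- sum(!ok)
  if (dropped)
    message(dropped, " record(s) with missing bioaccessible ",
            "concentration excluded from origin summary")
  res <- results[ok, ]
  if (!nrow(res)) stop("no complete records to summarise")
  groups <- split(res$bioaccessible_conc,
                  list(origin = res$origin, element = res$element),
                  drop = TRUE)
  keys <- do.call(rbind, strsplit(names(groups), ".", fixed = TRUE))
  out <- data.frame(origin = keys[, 1], element = keys[, 2],
                    n_batches = vapply(groups, length, 1L),
                    mean_conc = vapply(groups, mean, 1),
                    sd_conc = vapply(groups, function(v)
                      if (length(v) >= 2) stats::sd(v) else NA_real_, 1),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$origin, match(out$element, WORM_ELEMENTS)), ,
      drop = FALSE]
}

#' Mean bioaccessibility per element
#'
#' Per-element average of the per-sample bioaccessibility percent
#' (mean of ratios).  The ratio of mean bioaccessible to mean total
#' concentration is returned alongside for comparison; the two differ
#' whenever bioaccessibility covaries with concentration.
#'
#' @param results Output of [bioaccessible_content()].
#' @return Data frame `element`, `n`, `mean_pct` (mean of per-sample
#'   percents), `ratio_of_means_pct`, sorted by `mean_pct` descending.
#' @export
mean_bioaccessibility <- function(results) {
  stopifnot(all(c("element", "bioaccessibility_pct",
                  "bioaccessible_conc") %in% names(results)))
  ok <- !is.na(results$bioaccessibility_pct)
  res <- results[ok, ]
  if (!nrow(res)) stop("no samples with a bioaccessibility percent")
  els <- intersect(WORM_ELEMENTS, unique(res$element))
  out <- do.call(rbind, lapply(els, function(el) {
    sub <- res[res$element == el, ]
    data.frame(element = el, n = nrow(sub),
               mean_pct = mean(sub$bioaccessibility_pct),
               ratio_of_means_pct = 100 * mean(sub$bioaccessible_conc) /
                 mean(sub$bioaccessible_conc /
                        (sub$bioaccessibility_pct / 100)),
               stringsAsFactors = FALSE)
  }))
  out[order(-out$mean_pct), , drop = FALSE]
}

#' Export an origin summary as a wide "Mean +/- SD" CSV
#'
#' One row per origin, one column per element, cells formatted
#' `mean +/- sd` (mean only for single-batch origins).
#'
#' @param summary Output of [summarize_by_origin()].
#' @param path Output CSV path.
#' @param digits Significant digits for formatting (default 3).
#' @return `path`, invisibly.
#' @export
write_origin_table <- function(summary, path, digits = 3) {
  origins <- unique(summary$origin)
  els <- intersect(WORM_ELEMENTS, unique(summary$element))
  wide <- data.frame(origin = origins, stringsAsFactors = FALSE)
  wide$batches <- vapply(origins, function(o)
    max(summary$n_batches[summary$origin == o]), 1L)
  for (el in els) {
    wide[[el]] <- vapply(origins, function(o) {
      row <- summary[summary$origin == o & summary$element == el, ]
      if (!nrow(row)) return(NA_character_)
      m <- signif(row$mean_conc, digits)
      if (is.na(row$sd_conc)) format(m)
      else paste(format(m), "+/-", format(signif(row$sd_conc, digits)))
    }, character(1))
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
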