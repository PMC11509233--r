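#' Filter cascade configuration
#'
#' Settings for the standard SRS cleaning cascade: masked-code removal,
#' missing-value exclusion, study-window restriction, case-series
#' deduplication, and the minimum-case inclusion rule.
#'
#' @param study_start,study_end study window (inclusive both ends), `Date`
#'   or `YYYY-MM-DD` strings.  Defaults to the ten-year window
#'   2013-01-01 to 2022-12-31.
#' @param drop_masked drop reports carrying the masking ("MSK") flag, used
#'   by KAERS when a product has two or fewer manufacturers.
#' @param required_fields report fields whose absence excludes a report.
#'   Defaults to `"causality"` (the causality-evaluation result); any of
#'   `causality`, `sex`, `age_years`, `receipt_date` may be listed.
#' @param min_cases_per_drug minimum number of distinct case reports a drug
#'   must appear in to enter the analysis (default 3).
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(study_start = "2013-01-01",
                          study_end = "2022-12-31",
                          drop_masked = TRUE,
                          required_fields = "causality",
                          min_cases_per_drug = 3L) {
  study_start <- as.Date(study_start)
  study_end <- as.Date(study_end)
  stopifnot(study_start <= study_end, min_cases_per_drug >= 1)
  allowed <- c("causality", "sex", "age_years", "receipt_date")
  bad <- setdiff(required_fields, allowed)
  if (length(bad))
    stop("unsupported required field(s): ", paste(bad, collapse = ", "))
  structure(list(study_start = study_start, study_end = study_end,
                 drop_masked = isTRUE(drop_masked),
                 required_fields = required_fields,
                 min_cases_per_drug = as.integer(min_cases_per_drug)),
            class = "filter_config")
}

## Is the field unrecorded for each report?  "unknown" disposition is a real
## reported outcome category, so only the fields below have a missing state.
.field_missing <- function(reports, field) {
  v <- reports[[field]]
  switch(field,
         causality = is.na(v) | v == "missing",
         sex = is.na(v) | v == "unknown",
         is.na(v))
}

#' Remove masked reports
#'
#' Drops every report whose masking flag is set; masked rows are excluded to
#' avoid bias from products with too few manufacturers to be identifiable.
#'
#' @param ds an `srs_data` object.
#' @return filtered `srs_data` with a provenance entry appended.
#' @export
filter_masked <- function(ds) {
  stopifnot(inherits(ds, "srs_data"))
  keep <- !ds$reports$masked
  out <- ds
  out$reports <- ds$reports[keep, , drop = FALSE]
  rownames(out$reports) <- NULL
  .add_provenance(out, "filter_masked", length(keep), sum(keep))
}

#' Remove reports with missing required fields
#'
#' @param ds an `srs_data` object.
#' @param cfg a [filter_config()]; its `required_fields` entry names the
#'   fields whose absence excludes a report.
#' @return filtered `srs_data`; the provenance detail carries per-field
#'   removal tallies (a report missing several fields is removed once).
#' @export
filter_missing <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(ds, "srs_data"))
  fields <- cfg$required_fields
  n_in <- nrow(ds$reports)
  if (!length(fields)) {
    return(.add_provenance(ds, "filter_missing", n_in, n_in,
                           detail = "no required fields"))
  }
  miss <- vapply(fields, function(f) .field_missing(ds$reports, f),
                 logical(n_in))
  miss <- matrix(miss, nrow = n_in)
  drop <- rowSums(miss) > 0
  tallies <- colSums(miss)
  out <- ds
  out$reports <- ds$reports[!drop, , drop = FALSE]
  rownames(out$reports) <- NULL
  .add_provenance(out, "filter_missing", n_in, sum(!drop),
                  detail = paste(sprintf("%s:%d", fields, tallies),
                                 collapse = ", "))
}

#' Restrict to the study window
#'
#' Keeps reports whose receipt date lies inside `[study_start, study_end]`,
#' inclusive at both ends.
#'
#' @inheritParams filter_missing
#' @return filtered `srs_data`.
#' @export
filter_window <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(ds, "srs_data"))
  d <- ds$reports$receipt_date
  keep <- !is.na(d) & d >= cfg$study_start & d <= cfg$study_end
  out <- ds
  out$reports <- ds$reports[keep, , drop = FALSE]
  rownames(out$reports) <- NULL
  .add_provenance(out, "filter_window", length(keep), sum(keep))
}

#' Keep only the last report of each case series
#'
#' Successive versions of one case share a `series_id`; to avoid counting a
#' case more than once only the final version is retained.  "Last" is the
#' maximum under the lexicographic order (`sequence_no`, `receipt_date`,
#' `report_id`), which gives a unique, deterministic survivor even under
#' ties.
#'
#' @param ds an `srs_data` object.
#' @return deduplicated `srs_data` with pairwise-distinct `series_id`s.
#' @export
deduplicate_series <- function(ds) {
  stopifnot(inherits(ds, "srs_data"))
  rp <- ds$reports
  n_in <- nrow(rp)
  if (n_in == 0)
    return(.add_provenance(ds, "deduplicate_series", 0, 0))
  ord <- order(rp$series_id, rp$sequence_no, rp$receipt_date, rp$report_id)
  sorted <- rp[ord, , drop = FALSE]
  last <- !duplicated(sorted$series_id, fromLast = TRUE)
  keep_ids <- sorted$report_id[last]
  out <- ds
  out$reports <- rp[rp$report_id %in% keep_ids, , drop = FALSE]
  rownames(out$reports) <- NULL
  .add_provenance(out, "deduplicate_series", n_in, length(keep_ids))
}

#' Apply the minimum-case inclusion rule
#'
#' Drugs appearing in fewer than `min_cases_per_drug` distinct case reports
#' are removed from every report's drug list; reports left without any drug
#' are dropped.  Run after deduplication so "cases" means distinct cases.
#'
#' @inheritParams filter_missing
#' @return filtered `srs_data`.
#' @export
filter_min_cases <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(ds, "srs_data"))
  rp <- ds$reports
  n_in <- nrow(rp)
  drug_long <- data.frame(report = rep(rp$report_id, lengths(rp$drugs)),
                          drug = unlist(rp$drugs),
                          stringsAsFactors = FALSE)
  cases <- table(drug_long$drug)
  keep_drugs <- names(cases)[cases >= cfg$min_cases_per_drug]
  out <- ds
  out$reports <- rp
  out$reports$drugs <- lapply(rp$drugs, function(d) d[d %in% keep_drugs])
  nonempty <- lengths(out$reports$drugs) > 0
  out$reports <- out$reports[nonempty, , drop = FALSE]
  rownames(out$reports) <- NULL
  .add_provenance(out, "filter_min_cases", n_in, sum(nonempty),
                  detail = sprintf("%d drug code(s) below %d cases",
                                   length(cases) - length(keep_drugs),
                                   cfg$min_cases_per_drug))
}

#' Run the full filter cascade
#'
#' Applies, in order: masked-code removal (if configured), missing-value
#' exclusion, study-window restriction, case-series deduplication, and the
#' minimum-case rule.  The window filter precedes deduplication so that
#' "last report" is judged within the study period: a successor filed after
#' the window closes cannot evict an in-window report.
#'
#' The cascade is idempotent and each stage only removes records (or prunes
#' drug lists); the full provenance chain is retained on the result.
#'
#' @inheritParams filter_missing
#' @return filtered `srs_data`.
#' @export
run_filter_cascade <- function(ds, cfg = filter_config()) {
  stopifnot(inherits(ds, "srs_data"), inherits(cfg, "filter_config"))
  out <- if (cfg$drop_masked) filter_masked(ds) else ds
  out <- filter_missing(out, cfg)
  out <- filter_window(out, cfg)
  out <- deduplicate_series(out)
  filter_min_cases(out, cfg)
}
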