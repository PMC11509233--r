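#' @keywords internal
"_PACKAGE"

## Controlled vocabularies for report-level fields.  Codes arriving from a
## file that are not in these sets are mapped to the catch-all category
## ("other" or the field's missing level) rather than aborting a run.
.sex_levels         <- c("male", "female", "unknown")
.causality_levels   <- c("certain", "probable_likely", "possible", "other",
                         "missing")
.seriousness_levels <- c("hospitalization", "significant_medical_event",
                         "disability", "life_threatening", "death", "other",
                         "none")
.reporter_levels    <- c("pharma_company", "regional_pv_center",
                         "medical_professional", "other")
.report_type_levels <- c("study_research", "voluntary", "other")
.disposition_levels <- c("recovered", "not_recovered",
                         "recovered_with_sequelae", "unknown")

## Value that encodes "not recorded" for each demographic field.
.missing_level <- c(sex = "unknown", causality = "missing")

.report_columns <- c("report_id", "series_id", "sequence_no", "receipt_date",
                     "sex", "age_years", "causality", "seriousness",
                     "reporter_type", "report_type", "disposition", "masked")

#' Normalize a drug or event code
#'
#' Spontaneous-report data are entered inconsistently; codes are compared
#' after trimming surrounding whitespace and case-folding to lower case.
#'
#' @param x character vector of codes.
#' @return normalized character vector.
#' @export
normalize_code <- function(x) tolower(trimws(as.character(x)))

.map_enum <- function(x, levels, fallback) {
  x <- tolower(trimws(as.character(x)))
  x[is.na(x) | x == "" | !(x %in% levels)] <- fallback
  x
}

#' Construct a spontaneous reporting system dataset
#'
#' An `srs_data` object holds one row per case report together with an
#' append-only provenance trail recording every filtering step applied to
#' it.  Drugs and events are list columns (a report may carry several of
#' each); all other fields are report-level.
#'
#' @param reports data frame with columns `report_id`, `series_id`,
#'   `sequence_no`, `receipt_date` (`Date`), `sex`, `age_years`,
#'   `causality`, `seriousness`, `reporter_type`, `report_type`,
#'   `disposition`, `masked` (logical), and list columns `drugs`, `events`.
#' @param provenance optional data frame with columns `step`, `n_in`,
#'   `n_out`, `n_removed`, `detail`; defaults to an empty trail.
#'
#' @return an object of class `srs_data`.
#' @export
srs_data <- function(reports, provenance = NULL) {
  stopifnot(is.data.frame(reports))
  needed <- c(.report_columns, "drugs", "events")
  miss <- setdiff(needed, names(reports))
  if (length(miss))
    stop("reports is missing column(s): ", paste(miss, collapse = ", "))
  reports <- reports[, needed]
  rownames(reports) <- NULL

  if (anyDuplicated(reports$report_id))
    stop("report_id values must be unique within a dataset")
  key <- paste(reports$series_id, reports$sequence_no, sep = "\r")
  if (anyDuplicated(key))
    warning("duplicated (series_id, sequence_no) pairs present; ",
            "deduplicate_series() resolves them deterministically")

  reports$drugs  <- lapply(reports$drugs,  function(d) unique(normalize_code(d)))
  reports$events <- lapply(reports$events, function(e) unique(normalize_code(e)))
  if (any(lengths(reports$drugs) == 0) && nrow(reports) > 0)
    stop("every report must carry at least one drug code")
  if (any(lengths(reports$events) == 0) && nrow(reports) > 0)
    stop("every report must carry at least one event code")

  age <- reports$age_years
  if (any(!is.na(age) & (age < 0 | age > 150)))
    stop("age_years must lie in [0, 150] when present")

  if (is.null(provenance))
    provenance <- data.frame(step = character(), n_in = integer(),
                             n_out = integer(), n_removed = integer(),
                             detail = character(), stringsAsFactors = FALSE)
  structure(list(reports = reports, provenance = provenance),
            class = "srs_data")
}

#' Number of reports in a dataset
#' @param x an `srs_data` object.
#' @return integer report count.
#' @export
n_reports <- function(x) {
  stopifnot(inherits(x, "srs_data"))
  nrow(x$reports)
}

#' Provenance trail of a dataset
#'
#' Each filtering step appends one row with the step name, the record counts
#' before and after, and the number removed (`n_in = n_out + n_removed`).
#'
#' @param x an `srs_data` object.
#' @return data frame of provenance entries.
#' @export
provenance <- function(x) {
  stopifnot(inherits(x, "srs_data"))
  x$provenance
}

## Append a provenance row; enforces the count-reconciliation invariant.
.add_provenance <- function(x, step, n_in, n_out, detail = "") {
  n_removed <- n_in - n_out
  stopifnot(n_removed >= 0)
  row <- data.frame(step = step, n_in = as.integer(n_in),
                    n_out = as.integer(n_out),
                    n_removed = as.integer(n_removed),
                    detail = detail, stringsAsFactors = FALSE)
  x$provenance <- rbind(x$provenance, row)
  x
}

#' @export
print.srs_data <- function(x, ...) {
  cat("Spontaneous reporting system dataset\n")
  cat("  reports:", nrow(x$reports), "\n")
  cat("  drugs:  ", length(unique(unlist(x$reports$drugs))), "\n")
  cat("  events: ", length(unique(unlist(x$reports$events))), "\n")
  if (nrow(x$provenance)) {
    cat("  provenance:\n")
    for (i in seq_len(nrow(x$provenance)))
      cat(sprintf("    %-18s %7d -> %7d (-%d)\n", x$provenance$step[i],
                  x$provenance$n_in[i], x$provenance$n_out[i],
                  x$provenance$n_removed[i]))
  }
  invisible(x)
}

#' Flatten a dataset to the canonical long table
#'
#' The canonical interchange layout is one row per (report, drug, event)
#' occurrence with report-level fields repeated on every row; a report with
#' `d` drugs and `e` events expands to `d * e` rows.
#'
#' @param x an `srs_data` object.
#' @param row.names,optional,... ignored; present for method compatibility.
#' @return data frame in long layout.
#' @export
as.data.frame.srs_data <- function(x, row.names = NULL, optional = FALSE, ...) {
  rp <- x$reports
  nd <- lengths(rp$drugs)
  ne <- lengths(rp$events)
  idx <- rep(seq_len(nrow(rp)), nd * ne)
  drug <- unlist(mapply(function(d, k) rep(d, each = k), rp$drugs, ne,
                        SIMPLIFY = FALSE), use.names = FALSE)
  event <- unlist(mapply(function(e, k) rep(e, times = k), rp$events, nd,
                         SIMPLIFY = FALSE), use.names = FALSE)
  out <- data.frame(report_id = rp$report_id[idx],
                    series_id = rp$series_id[idx],
                    sequence_no = rp$sequence_no[idx],
                    receipt_date = rp$receipt_date[idx],
                    drug = drug, event = event,
                    sex = rp$sex[idx], age_years = rp$age_years[idx],
                    causality = rp$causality[idx],
                    seriousness = rp$seriousness[idx],
                    reporter_type = rp$reporter_type[idx],
                    report_type = rp$report_type[idx],
                    disposition = rp$disposition[idx],
                    masked = rp$masked[idx],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
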