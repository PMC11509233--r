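#' Read report-level adverse event tables
#'
#' Reads the canonical long layout (one row per (report, drug, event)
#' occurrence, report-level fields repeated per row; see
#' [as.data.frame.srs_data()]) and folds rows sharing a `report_id` into one
#' report whose drug and event lists are the unions of the row values.
#'
#' Dates must be ISO-8601 (`YYYY-MM-DD`).  Rows whose date cannot be parsed
#' are skipped, counted, and reported with a warning.  Duplicate
#' (report, drug, event) rows are deduplicated silently with a logged count.
#' Field values outside the controlled vocabularies map to the catch-all
#' category ("other", or "missing"/"unknown" for causality/sex).
#'
#' @param path path to a delimited text file (UTF-8, header required).
#' @param delim field delimiter; tab by default.
#' @return an `srs_data` object with its provenance initialized with the raw
#'   row and report counts.
#' @seealso [write_srs_reports()] for the inverse operation.
#' @export
read_srs_reports <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", comment.char = "",
                           check.names = FALSE, fileEncoding = "UTF-8")
  mandatory <- c("report_id", "series_id", "sequence_no", "receipt_date",
                 "drug", "event", "sex", "age_years", "causality",
                 "seriousness", "reporter_type", "report_type",
                 "disposition", "masked")
  miss <- setdiff(mandatory, names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))

  n_rows_raw <- nrow(raw)
  detail <- character()

  if (n_rows_raw) {
    raw$drug  <- normalize_code(raw$drug)
    raw$event <- normalize_code(raw$event)
    triple <- paste(raw$report_id, raw$drug, raw$event, sep = "\r")
    dup <- duplicated(triple)
    if (any(dup)) {
      detail <- c(detail, sprintf("%d duplicate (report,drug,event) rows dropped",
                                  sum(dup)))
      raw <- raw[!dup, , drop = FALSE]
    }
  }

  date <- as.Date(raw$receipt_date, format = "%Y-%m-%d")
  bad_date_ids <- unique(raw$report_id[is.na(date) & nrow(raw) > 0])
  ids <- unique(raw$report_id)
  n_records_total <- length(ids)
  if (length(bad_date_ids)) {
    warning(sprintf("%d report(s) skipped due to unparseable receipt_date: %s",
                    length(bad_date_ids),
                    paste(utils::head(bad_date_ids, 5), collapse = ", ")))
    detail <- c(detail, sprintf("%d reports skipped (unparseable date)",
                                length(bad_date_ids)))
    keep <- !(raw$report_id %in% bad_date_ids)
    raw <- raw[keep, , drop = FALSE]
    date <- date[keep]
    ids <- setdiff(ids, bad_date_ids)
  }

  if (length(ids)) {
    first <- raw[!duplicated(raw$report_id), , drop = FALSE]
    ord <- match(ids, first$report_id)
    first <- first[ord, , drop = FALSE]
    fidx <- factor(raw$report_id, levels = ids)
    drugs  <- split(raw$drug, fidx)
    events <- split(raw$event, fidx)
    reports <- data.frame(
      report_id = first$report_id,
      series_id = first$series_id,
      sequence_no = suppressWarnings(as.integer(first$sequence_no)),
      receipt_date = as.Date(first$receipt_date, format = "%Y-%m-%d"),
      sex = .map_enum(first$sex, .sex_levels, "unknown"),
      age_years = suppressWarnings(as.numeric(first$age_years)),
      causality = .map_enum(first$causality, .causality_levels, "missing"),
      seriousness = vapply(strsplit(first$seriousness, ";", fixed = TRUE),
                           function(s) paste(.map_enum(s, .seriousness_levels,
                                                       "other"),
                                             collapse = ";"), character(1)),
      reporter_type = .map_enum(first$reporter_type, .reporter_levels, "other"),
      report_type = .map_enum(first$report_type, .report_type_levels, "other"),
      disposition = .map_enum(first$disposition, .disposition_levels, "unknown"),
      masked = toupper(trimws(first$masked)) %in% c("TRUE", "T", "1", "MSK", "YES", "Y"),
      stringsAsFactors = FALSE)
    reports$drugs  <- unname(lapply(drugs,  function(d) unique(d)))
    reports$events <- unname(lapply(events, function(e) unique(e)))
  } else {
    reports <- data.frame(report_id = character(), series_id = character(),
                          sequence_no = integer(),
                          receipt_date = as.Date(character()),
                          sex = character(), age_years = numeric(),
                          causality = character(), seriousness = character(),
                          reporter_type = character(),
                          report_type = character(),
                          disposition = character(), masked = logical(),
                          stringsAsFactors = FALSE)
    reports$drugs <- list()
    reports$events <- list()
  }

  ds <- srs_data(reports)
  .add_provenance(ds, "ingest", n_records_total, length(ids),
                  detail = paste(c(sprintf("%d raw rows", n_rows_raw), detail),
                                 collapse = "; "))
}

#' Write a dataset to the canonical long table
#'
#' @param x an `srs_data` object.
#' @param path output file path.
#' @param delim field delimiter; tab by default.
#' @return `path`, invisibly.
#' @export
write_srs_reports <- function(x, path, delim = "\t") {
  stopifnot(inherits(x, "srs_data"))
  write_delim_table(as.data.frame(x), path, delim = delim)
}

#' Write a flat table as delimited text
#'
#' Header row, stable column order, quoted fields where needed; round-trips
#' through `utils::read.table` without loss.
#'
#' @param rows data frame of flat records (all rows share the field set).
#' @param path output file path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_delim_table <- function(rows, path, delim = "\t") {
  stopifnot(is.data.frame(rows))
  con <- tryCatch(file(path, open = "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  utils::write.table(rows, con, sep = delim, quote = TRUE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}

#' Read a label-expectedness reference
#'
#' Three-column delimited file (`drug`, `event`, `source`) listing
#' drug-event pairs that appear on the product label, per source authority
#' (MFDS or FDA).  Duplicate rows collapse to a single entry.
#'
#' @param path path to the reference file.
#' @param delim field delimiter; tab by default.
#' @return data frame of class `expectedness_ref` with columns `drug`,
#'   `event`, `source`.
#' @export
read_expectedness <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           colClasses = "character", comment.char = "",
                           fileEncoding = "UTF-8")
  miss <- setdiff(c("drug", "event", "source"), names(raw))
  if (length(miss))
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  src <- toupper(trimws(raw$source))
  bad <- setdiff(unique(src), c("MFDS", "FDA"))
  if (length(bad))
    stop("unknown expectedness source(s): ", paste(bad, collapse = ", "),
         " (allowed: MFDS, FDA)")
  out <- data.frame(drug = normalize_code(raw$drug),
                    event = normalize_code(raw$event),
                    source = src, stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("expectedness_ref", "data.frame")
  out
}
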