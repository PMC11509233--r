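#' Round half away from zero
#'
#' Published pharmacovigilance tables round half-up (5 rounds away from
#' zero), unlike R's banker's rounding; percentages here use 1 decimal and
#' statistics 2 decimals.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.age_breaks <- c(0, 20, 40, 60, 80, 100, Inf)
.age_labels <- c("<20", "20-39", "40-59", "60-79", "80-99", ">=100")

#' Summarise the demographics of a report dataset
#'
#' Tabulates sex, age group, causality, reporter type, report type, final
#' disposition, and seriousness, with counts and half-up-rounded
#' percentages, in the style of the demographic table of an SRS study.
#'
#' Denominator policy: with `denominators = "mixed"` (default, matching the
#' arithmetic such tables print) sex and age use the number of reports with
#' the field recorded, while causality and the administrative fields use
#' the total report count -- so a field with heavy missingness shows
#' categories summing below 100% unless its missing category is displayed.
#' With `"known"` every field uses its recorded-value count.
#'
#' @param ds an `srs_data` object (normally post-cascade).
#' @param denominators `"mixed"` (default) or `"known"`.
#' @return an object of class `demographic_summary`: a list with `fields`
#'   (per field, a data frame of `category`, `count`, `percent`),
#'   `denominators`, and `n_total`.
#' @export
summarize_demographics <- function(ds, denominators = c("mixed", "known")) {
  stopifnot(inherits(ds, "srs_data"))
  denominators <- match.arg(denominators)
  rp <- ds$reports
  n_total <- nrow(rp)

  age_group <- as.character(cut(rp$age_years, breaks = .age_breaks,
                                labels = .age_labels, right = FALSE))
  vals <- list(
    sex = rp$sex,
    age_group = age_group,
    causality = rp$causality,
    reporter_type = rp$reporter_type,
    report_type = rp$report_type,
    disposition = rp$disposition,
    seriousness = unlist(lapply(strsplit(rp$seriousness, ";", fixed = TRUE),
                                unique)))
  missing_mask <- list(
    sex = .field_missing(rp, "sex"),
    age_group = is.na(age_group),
    causality = .field_missing(rp, "causality"),
    reporter_type = rep(FALSE, n_total),
    report_type = rep(FALSE, n_total),
    disposition = rep(FALSE, n_total),
    seriousness = NULL)
  known_only <- c("sex", "age_group")           # fields tabulated over
                                                # recorded values in mixed mode
  fields <- list()
  dens <- integer()
  for (f in names(vals)) {
    v <- vals[[f]]
    if (f == "seriousness") {
      den <- n_total
      tab <- table(v)
    } else {
      m <- missing_mask[[f]]
      use_known <- denominators == "known" || f %in% known_only
      den <- if (use_known) sum(!m) else n_total
      tab <- if (use_known) table(v[!m]) else table(v)
    }
    df <- data.frame(category = names(tab), count = as.integer(tab),
                     stringsAsFactors = FALSE)
    df$percent <- if (den > 0) round_half_up(100 * df$count / den, 1) else 0
    rownames(df) <- NULL
    fields[[f]] <- df
    dens[f] <- den
  }
  structure(list(fields = fields, denominators = dens, n_total = n_total),
            class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat(sprintf("Demographics of %d reports\n", x$n_total))
  for (f in names(x$fields)) {
    cat(sprintf("%s (n = %d)\n", f, x$denominators[[f]]))
    df <- x$fields[[f]]
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-28s %6d (%.1f%%)\n", df$category[i], df$count[i],
                  df$percent[i]))
  }
  invisible(x)
}

#' Expand published demographic summary counts into a report-level dataset
#'
#' Reconstructs a synthetic report-level dataset whose per-field category
#' counts equal a published summary table, so that summary arithmetic
#' (denominators, rounding) can be recomputed through the same code path as
#' for real data.  Fields are assigned to reports independently, category
#' by category in order, which preserves every marginal count but carries
#' no joint structure; drugs/events are placeholders.
#'
#' @param counts data frame with columns `field`, `category`, `count`;
#'   `field` one of `sex`, `age_group`, `causality`, `reporter_type`,
#'   `report_type`, `disposition`.  Categories absent for a field are
#'   filled with its missing/unknown level.
#' @param n_total total number of reports (must be >= every field's count
#'   sum).
#' @return an `srs_data` object with `n_total` records.
#' @export
dataset_from_demographic_counts <- function(counts, n_total) {
  stopifnot(is.data.frame(counts),
            all(c("field", "category", "count") %in% names(counts)))
  n_total <- as.integer(n_total)
  fill <- function(field, missing_level) {
    sub <- counts[counts$field == field, , drop = FALSE]
    if (sum(sub$count) > n_total)
      stop("counts for '", field, "' exceed n_total")
    v <- rep(missing_level, n_total)
    if (nrow(sub)) {
      at <- c(0, cumsum(sub$count))
      for (i in seq_len(nrow(sub)))
        if (sub$count[i] > 0)
          v[(at[i] + 1):at[i + 1]] <- sub$category[i]
    }
    v
  }
  age_group <- fill("age_group", NA_character_)
  mid <- c("<20" = 10, "20-39" = 30, "40-59" = 50, "60-79" = 70,
           "80-99" = 90, ">=100" = 100)
  reports <- data.frame(
    report_id = sprintf("R%06d", seq_len(n_total)),
    series_id = sprintf("S%06d", seq_len(n_total)),
    sequence_no = 1L,
    receipt_date = as.Date("2018-01-01"),
    sex = fill("sex", "unknown"),
    age_years = as.numeric(mid[age_group]),
    causality = fill("causality", "missing"),
    seriousness = fill("seriousness", "none"),
    reporter_type = fill("reporter_type", "other"),
    report_type = fill("report_type", "other"),
    disposition = fill("disposition", "unknown"),
    masked = FALSE, stringsAsFactors = FALSE)
  reports$drugs <- rep(list("drug_x"), n_total)
  reports$events <- rep(list("event_x"), n_total)
  srs_data(reports)
}

#' Per-drug signal table with label-expectedness annotation
#'
#' One row per analyzed event for the given drug, sorted by event:
#' report count (cell A), PRR, ROR and IC025 rendered at 2 decimals, the
#' per-criterion and definitive flags (computed on the unrounded
#' statistics), and whether each source authority lists the event on the
#' drug's label.
#'
#' Expectedness is `"Y"` when the (drug, event, source) triple is in the
#' reference, `"N"` when the reference carries other entries for that drug
#' and source (the label was consulted and the event is not on it), and
#' `"unknown"` when the reference has nothing for that drug and source.
#'
#' @param x a `disprop` object.
#' @param drug drug code.
#' @param expectedness optional `expectedness_ref` from
#'   [read_expectedness()].
#' @return data frame with columns `event`, `n_reports`, `prr`, `ror`,
#'   `ic_lci95`, `prr_signal`, `ror_signal`, `ic_signal`,
#'   `definitive_signal`, `expected_mfds`, `expected_fda`.  Unknown drugs
#'   yield an empty table.
#' @export
build_signal_table <- function(x, drug, expectedness = NULL) {
  stopifnot(inherits(x, "disprop"))
  drug <- normalize_code(drug)
  r <- x$results[x$results$drug == drug, , drop = FALSE]
  r <- r[order(r$event), , drop = FALSE]
  lookup <- function(src) {
    if (is.null(expectedness)) return(rep("unknown", nrow(r)))
    ref <- expectedness[expectedness$source == src &
                        expectedness$drug == drug, , drop = FALSE]
    if (!nrow(ref)) return(rep("unknown", nrow(r)))
    ifelse(r$event %in% ref$event, "Y", "N")
  }
  out <- data.frame(event = r$event, n_reports = r$A,
                    prr = round_half_up(r$prr, 2),
                    ror = round_half_up(r$ror, 2),
                    ic_lci95 = round_half_up(r$ic_lci95, 2),
                    prr_signal = r$prr_signal, ror_signal = r$ror_signal,
                    ic_signal = r$ic_signal,
                    definitive_signal = r$definitive_signal,
                    expected_mfds = lookup("MFDS"),
                    expected_fda = lookup("FDA"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Validate a positive-control association
#'
#' A positive control is a drug-event association established well enough
#' that the detection machinery must flag it; failure indicates a data or
#' method problem rather than an absent association.
#'
#' @param x a `disprop` object.
#' @param control_drug,control_event codes of the control pair.
#' @return a list of class `pv_control_verdict` with elements `verdict`
#'   (`"pass"`, `"fail"`, or `"not_evaluable"` when the pair was filtered
#'   out before analysis), `drug`, `event`, and `statistics` (the pair's
#'   result row, or `NULL`).
#' @export
validate_positive_control <- function(x, control_drug, control_event) {
  stopifnot(inherits(x, "disprop"))
  d <- normalize_code(control_drug)
  e <- normalize_code(control_event)
  row <- x$results[x$results$drug == d & x$results$event == e, ,
                   drop = FALSE]
  verdict <- if (!nrow(row)) "not_evaluable"
             else if (row$definitive_signal) "pass" else "fail"
  structure(list(verdict = verdict, drug = d, event = e,
                 statistics = if (nrow(row)) row else NULL),
            class = "pv_control_verdict")
}

#' @export
print.pv_control_verdict <- function(x, ...) {
  cat(sprintf("Positive control %s / %s: %s\n", x$drug, x$event,
              toupper(x$verdict)))
  if (!is.null(x$statistics)) {
    s <- x$statistics
    cat(sprintf("  A = %d, PRR = %.2f, ROR = %.2f, IC025 = %.2f\n",
                s$A, s$prr, s$ror, s$ic_lci95))
  }
  invisible(x)
}

#' Heatmap matrix of the signal statistics for one drug
#'
#' Rectangular grid with the drug's events as rows and the three indices
#' (PRR, ROR, IC025) as columns; the `"signal"` attribute is a logical
#' matrix marking cells whose index criterion fired (a row marked in all
#' three columns is a definitive signal).  Serialise with
#' [write_delim_table()]; [plot.disprop()] renders it.
#'
#' @param x a `disprop` object.
#' @param drug drug code.
#' @return numeric matrix (events x 3) with a `"signal"` attribute.
#' @export
heatmap_matrix <- function(x, drug) {
  stopifnot(inherits(x, "disprop"))
  drug <- normalize_code(drug)
  r <- x$results[x$results$drug == drug, , drop = FALSE]
  r <- r[order(r$event), , drop = FALSE]
  m <- cbind(PRR = r$prr, ROR = r$ror, IC_LCI95 = r$ic_lci95)
  rownames(m) <- r$event
  sig <- cbind(r$prr_signal, r$ror_signal, r$ic_signal)
  dimnames(sig) <- dimnames(m)
  attr(m, "signal") <- sig
  m
}
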