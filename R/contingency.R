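#' Expand reports into drug-event units
#'
#' The counting unit of the disproportionality analysis is the distinct
#' (report, drug, event) triple: a report carrying `d` drugs and `e` events
#' contributes `d * e` units.
#'
#' @param ds an `srs_data` object (normally post-cascade).
#' @return data frame with columns `report_id`, `drug`, `event`, one row per
#'   distinct triple.
#' @export
expand_pairs <- function(ds) {
  stopifnot(inherits(ds, "srs_data"))
  long <- as.data.frame(ds)
  units <- long[, c("report_id", "drug", "event")]
  units <- unique(units)
  rownames(units) <- NULL
  units
}

## Cross-tabulate units into the full A-count matrix plus margins.
.unit_counts <- function(units, counting_unit) {
  if (counting_unit == "report") {
    ## any-mention semantics: each report counts once per cell; since a
    ## report mentions (d, e) iff the triple exists, distinct triples per
    ## pair equal distinct reports per pair
    n_total <- length(unique(units$report_id))
    A <- table(factor(units$drug), factor(units$event))
    rd <- unique(units[, c("report_id", "drug")])
    re <- unique(units[, c("report_id", "event")])
    drug_margin <- table(factor(rd$drug, levels = rownames(A)))
    event_margin <- table(factor(re$event, levels = colnames(A)))
  } else {
    A <- table(factor(units$drug), factor(units$event))
    drug_margin <- rowSums(A)
    event_margin <- colSums(A)
    n_total <- nrow(units)
  }
  list(A = A, drug_margin = as.numeric(drug_margin),
       event_margin = as.numeric(event_margin), N = n_total)
}

#' Build 2x2 contingency tables for all observed drug-event pairs
#'
#' For each pair, cell `A` counts units with the target drug and target
#' event, `B` the target drug with any other event, `C` any other drug with
#' the target event, and `D` the remainder; `N = A + B + C + D`.
#'
#' With `counting_unit = "pair"` (the dominant convention in
#' spontaneous-report disproportionality) the unit is the distinct
#' (report, drug, event) triple; with `"report"` each report counts once per
#' cell under any-mention semantics.
#'
#' @param x an `srs_data` object or a unit data frame from [expand_pairs()].
#' @param counting_unit `"pair"` (default) or `"report"`.
#' @return data frame of class `contingency_set` with columns `drug`,
#'   `event`, `A`, `B`, `C`, `D`, one row per observed pair, ordered by
#'   (drug, event); the total `N` and the counting unit are attached as
#'   attributes.
#' @export
contingency_tables <- function(x, counting_unit = c("pair", "report")) {
  counting_unit <- match.arg(counting_unit)
  units <- if (inherits(x, "srs_data")) expand_pairs(x) else x
  stopifnot(is.data.frame(units),
            all(c("report_id", "drug", "event") %in% names(units)))
  if (nrow(units) == 0) stop("no drug-event units to tabulate")
  cnt <- .unit_counts(units, counting_unit)
  A <- cnt$A
  obs <- which(A > 0, arr.ind = TRUE)
  a <- as.numeric(A[obs])
  b <- cnt$drug_margin[obs[, 1]] - a
  c_ <- cnt$event_margin[obs[, 2]] - a
  d <- cnt$N - a - b - c_
  out <- data.frame(drug = rownames(A)[obs[, 1]],
                    event = colnames(A)[obs[, 2]],
                    A = as.integer(a), B = as.integer(b),
                    C = as.integer(c_), D = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(out$drug, out$event), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- as.integer(cnt$N)
  attr(out, "counting_unit") <- counting_unit
  class(out) <- c("contingency_set", "data.frame")
  out
}

#' Build the 2x2 table for a single drug-event pair
#'
#' @inheritParams contingency_tables
#' @param drug,event target codes (normalized before lookup).
#' @return named numeric vector with elements `A`, `B`, `C`, `D`, `N`.  A
#'   pair absent from the data yields `A = 0` (not an error).
#' @export
contingency_table <- function(x, drug, event,
                              counting_unit = c("pair", "report")) {
  counting_unit <- match.arg(counting_unit)
  units <- if (inherits(x, "srs_data")) expand_pairs(x) else x
  drug <- normalize_code(drug)
  event <- normalize_code(event)
  if (counting_unit == "report") {
    ids_d <- unique(units$report_id[units$drug == drug])
    ids_e <- unique(units$report_id[units$event == event])
    a <- length(intersect(ids_d, ids_e))
    b <- length(ids_d) - a
    c_ <- length(ids_e) - a
    n <- length(unique(units$report_id))
  } else {
    is_d <- units$drug == drug
    is_e <- units$event == event
    a <- sum(is_d & is_e)
    b <- sum(is_d & !is_e)
    c_ <- sum(!is_d & is_e)
    n <- nrow(units)
  }
  c(A = a, B = b, C = c_, D = n - a - b - c_, N = n)
}
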