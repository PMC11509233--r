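# Builders for report-level fixtures and brute-force oracles used across
# the suite.  All fixtures are generated in code; nothing is read from disk
# unless a test writes it first.

make_report <- function(id, series = id, seq = 1L, date = "2018-06-01",
                        sex = "male", age = 40, causality = "possible",
                        seriousness = "none",
                        reporter = "pharma_company", rtype = "voluntary",
                        dispo = "recovered", masked = FALSE,
                        drugs = "apix", events = "e1") {
  list(report_id = id, series_id = series, sequence_no = as.integer(seq),
       receipt_date = as.Date(date), sex = sex, age_years = age,
       causality = causality, seriousness = seriousness,
       reporter_type = reporter, report_type = rtype, disposition = dispo,
       masked = masked, drugs = list(drugs), events = list(events))
}

make_dataset <- function(records) {
  flat <- lapply(records, function(r) {
    df <- data.frame(r[setdiff(names(r), c("drugs", "events"))],
                     stringsAsFactors = FALSE)
    df$drugs <- r$drugs
    df$events <- r$events
    df
  })
  srs_data(do.call(rbind, flat))
}

# 50-record fixture engineered so each cascade stage removes a known count:
# 5 masked, 4 missing causality, 3 outside the study window, 4 series
# duplicates, 2 reports lost to the minimum-case rule (final n = 32).
cascade_fixture <- function() {
  recs <- list()
  for (i in 1:5)
    recs[[length(recs) + 1]] <- make_report(sprintf("R%02d", i), masked = TRUE)
  for (i in 6:9)
    recs[[length(recs) + 1]] <- make_report(sprintf("R%02d", i),
                                            causality = "missing")
  recs[[length(recs) + 1]] <- make_report("R10", date = "2012-12-31")
  recs[[length(recs) + 1]] <- make_report("R11", date = "2023-01-01")
  recs[[length(recs) + 1]] <- make_report("R12", date = "2012-06-15")
  recs[[length(recs) + 1]] <- make_report("R13", series = "SD1", seq = 1)
  recs[[length(recs) + 1]] <- make_report("R14", series = "SD1", seq = 2)
  recs[[length(recs) + 1]] <- make_report("R15", series = "SD2", seq = 1)
  recs[[length(recs) + 1]] <- make_report("R16", series = "SD2", seq = 2)
  recs[[length(recs) + 1]] <- make_report("R17", series = "SD2", seq = 3)
  recs[[length(recs) + 1]] <- make_report("R18", series = "SD3", seq = 1,
                                          date = "2018-01-01")
  recs[[length(recs) + 1]] <- make_report("R19", series = "SD3", seq = 2,
                                          date = "2018-02-01")
  recs[[length(recs) + 1]] <- make_report("R20", drugs = "rare1")
  recs[[length(recs) + 1]] <- make_report("R21", drugs = c("rare1", "apix"))
  recs[[length(recs) + 1]] <- make_report("R22", drugs = "rare2")
  for (i in 23:50)
    recs[[length(recs) + 1]] <- make_report(sprintf("R%02d", i))
  make_dataset(recs)
}

# Brute-force 2x2 cells for one pair from a distinct-triple unit table.
bf_cells_pair <- function(units, drug, event) {
  is_d <- units$drug == drug
  is_e <- units$event == event
  c(A = sum(is_d & is_e), B = sum(is_d & !is_e),
    C = sum(!is_d & is_e), D = sum(!is_d & !is_e))
}

bf_cells_report <- function(units, drug, event) {
  rd <- unique(units$report_id[units$drug == drug])
  re <- unique(units$report_id[units$event == event])
  n <- length(unique(units$report_id))
  a <- length(intersect(rd, re))
  c(A = a, B = length(rd) - a, C = length(re) - a,
    D = n - length(rd) - length(re) + a)
}

# Random distinct-triple unit table.
random_units <- function(n, n_drugs = 4, n_events = 5, seed = 1) {
  set.seed(seed)
  u <- data.frame(report_id = sprintf("R%03d", sample(60, n, replace = TRUE)),
                  drug = sprintf("d%d", sample(n_drugs, n, replace = TRUE)),
                  event = sprintf("e%d", sample(n_events, n, replace = TRUE)),
                  stringsAsFactors = FALSE)
  unique(u)
}

# Random strictly-positive 2x2 tables (valid margins for every statistic).
random_tables <- function(n, seed = 1, a_range = 1:500) {
  set.seed(seed)
  data.frame(A = sample(a_range, n, replace = TRUE),
             B = sample(1:500, n, replace = TRUE),
             C = sample(1:500, n, replace = TRUE),
             D = sample(1:10000, n, replace = TRUE))
}

# Unit table realizing given pair counts: one synthetic report per unit.
units_from_counts <- function(counts) {
  # counts: data.frame(drug, event, n)
  idx <- rep(seq_len(nrow(counts)), counts$n)
  data.frame(report_id = sprintf("U%05d", seq_along(idx)),
             drug = counts$drug[idx], event = counts$event[idx],
             stringsAsFactors = FALSE)
}
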