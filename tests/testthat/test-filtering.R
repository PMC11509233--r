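test_that("masked-report removal drops exactly the flagged reports", {
  recs <- lapply(1:10, function(i) make_report(sprintf("R%02d", i),
                                               masked = i <= 3))
  ds <- make_dataset(recs)
  out <- filter_masked(ds)
  expect_equal(n_reports(out), 7)
  pv <- provenance(out)
  expect_equal(pv$n_in[nrow(pv)], 10L)
  expect_equal(pv$n_out[nrow(pv)], 7L)

  # no masked reports: identity on records, provenance still appended
  clean <- make_dataset(lapply(1:4, function(i) make_report(paste0("C", i))))
  out2 <- filter_masked(clean)
  expect_equal(out2$reports, clean$reports)
  expect_equal(nrow(provenance(out2)), nrow(provenance(clean)) + 1)

  # all masked: empty dataset accepted by downstream stages
  allm <- make_dataset(lapply(1:3, function(i) make_report(paste0("M", i),
                                                           masked = TRUE)))
  out3 <- run_filter_cascade(allm)
  expect_equal(n_reports(out3), 0)
})

test_that("missing-value exclusion respects required fields and tallies", {
  recs <- list(make_report("R1"), make_report("R2"),
               make_report("R3", causality = "missing"),
               make_report("R4", causality = "missing"),
               make_report("R5"))
  ds <- make_dataset(recs)
  out <- filter_missing(ds, filter_config(required_fields = "causality"))
  expect_equal(n_reports(out), 3)

  # empty required set is the identity
  out2 <- filter_missing(ds, filter_config(required_fields = character()))
  expect_equal(out2$reports, ds$reports)

  # a report missing both fields is removed once; per-field tallies both count it
  recs6 <- list(make_report("A1"), make_report("A2", sex = "unknown"),
                make_report("A3", causality = "missing"),
                make_report("A4", sex = "unknown", causality = "missing"),
                make_report("A5"), make_report("A6"))
  ds6 <- make_dataset(recs6)
  out3 <- filter_missing(ds6, filter_config(required_fields = c("sex", "causality")))
  expect_equal(n_reports(out3), 3)
  pv <- provenance(out3)
  expect_equal(pv$n_removed[nrow(pv)], 3L)
  expect_match(pv$detail[nrow(pv)], "sex:2")
  expect_match(pv$detail[nrow(pv)], "causality:2")
})

test_that("study-window restriction is inclusive at both ends", {
  cfg <- filter_config(study_start = "2013-01-01", study_end = "2022-12-31")
  recs <- list(make_report("R1", date = "2022-12-31"),  # end boundary: kept
               make_report("R2", date = "2013-01-01"),  # start boundary: kept
               make_report("R3", date = "2012-12-31"),  # day before: removed
               make_report("R4", date = "2023-01-01"),
               make_report("R5", date = "2018-05-05"),
               make_report("R6", date = "2010-01-01"),
               make_report("R7", date = "2020-02-02"),
               make_report("R8", date = "2021-03-03"))
  ds <- make_dataset(recs)
  out <- filter_window(ds, cfg)
  expect_equal(n_reports(out), 5)
  expect_true(all(c("R1", "R2") %in% out$reports$report_id))
  expect_false(any(c("R3", "R4", "R6") %in% out$reports$report_id))
})

test_that("deduplication keeps the unique maximal record per series", {
  # ordinary case: highest sequence_no survives
  ds <- make_dataset(list(make_report("R1", series = "S", seq = 1),
                          make_report("R2", series = "S", seq = 2),
                          make_report("R3", series = "S", seq = 3)))
  out <- deduplicate_series(ds)
  expect_equal(out$reports$report_id, "R3")

  # singleton series: identity
  ds2 <- make_dataset(list(make_report("A"), make_report("B"),
                           make_report("C")))
  expect_equal(deduplicate_series(ds2)$reports, ds2$reports)

  # exhaustive permutations of a 3-record series with ties: the survivor is
  # unique and input-order independent at every tie depth
  cases <- list(
    list(seqs = c(1, 2, 3), dates = rep("2018-01-01", 3), winner = "Rc"),
    list(seqs = c(2, 2, 1), dates = c("2018-01-01", "2018-03-01",
                                      "2018-06-01"), winner = "Rb"),
    list(seqs = c(2, 2, 2), dates = rep("2018-01-01", 3), winner = "Rc"))
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), 3:1)
  for (cs in cases) {
    recs <- mapply(function(id, sq, dt)
      make_report(id, series = "S", seq = sq, date = dt),
      c("Ra", "Rb", "Rc"), cs$seqs, cs$dates, SIMPLIFY = FALSE)
    for (p in perms) {
      ds3 <- suppressWarnings(make_dataset(recs[p]))
      out3 <- suppressWarnings(deduplicate_series(ds3))
      expect_equal(out3$reports$report_id, cs$winner)
    }
  }
})

test_that("minimum-case rule prunes drugs and cascades to empty reports", {
  cfg <- filter_config(min_cases_per_drug = 3)
  recs <- list(make_report("R1", drugs = c("common", "rare")),
               make_report("R2", drugs = "rare"),
               make_report("R3", drugs = "common"),
               make_report("R4", drugs = "common"),
               make_report("R5", drugs = "solo"))
  ds <- make_dataset(recs)
  out <- filter_min_cases(ds, cfg)
  # rare (2 cases) and solo (1 case) are pruned everywhere; R2 and R5 drop
  expect_equal(sort(out$reports$report_id), c("R1", "R3", "R4"))
  expect_false("rare" %in% unlist(out$reports$drugs))

  # boundary: exactly min_cases cases retained
  ds3 <- make_dataset(lapply(1:3, function(i) make_report(paste0("B", i),
                                                          drugs = "borderline")))
  expect_equal(n_reports(filter_min_cases(ds3, cfg)), 3)
})

test_that("the full cascade reproduces a hand-traced fixture and reconciles", {
  ds <- cascade_fixture()
  out <- run_filter_cascade(ds)
  pv <- provenance(out)
  expect_equal(pv$step, c("filter_masked", "filter_missing", "filter_window",
                          "deduplicate_series", "filter_min_cases"))
  expect_equal(pv$n_removed, c(5L, 4L, 3L, 4L, 2L))
  expect_equal(n_reports(out), 32)
  # monotone counts; removals reconcile with initial minus final
  expect_true(all(diff(pv$n_out) <= 0))
  expect_equal(sum(pv$n_removed), n_reports(ds) - n_reports(out))
  expect_true(all(pv$n_in == pv$n_out + pv$n_removed))
  # survivors are a subset of the input
  expect_true(all(out$reports$report_id %in% ds$reports$report_id))
  # deduplicated series ids are pairwise distinct
  expect_false(anyDuplicated(out$reports$series_id) > 0)
})

test_that("the cascade is idempotent and the identity on clean data", {
  ds <- cascade_fixture()
  once <- run_filter_cascade(ds)
  twice <- run_filter_cascade(once)
  expect_equal(twice$reports, once$reports)
  expect_true(all(provenance(twice)$n_removed[6:10] == 0))

  clean <- make_dataset(lapply(1:5, function(i) make_report(paste0("K", i))))
  out <- run_filter_cascade(clean)
  expect_equal(out$reports, clean$reports)
})
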