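# Frozen oracle values on the reference table A=10, B=90, C=100, D=9900
# were computed by direct arithmetic on the defining formulas:
#   PRR = (10/100)/(100/10000) = 10
#   ROR = 10*9900/(90*100) = 11
#   Woolf CI = exp(ln 11 -+ 1.96 sqrt(1/10+1/90+1/100+1/9900))
#   chi2 = 10100*(10*9900-90*100)^2/(100*10000*110*9990)
#   IC_raw = log2(10*10100/(100*110)); E = 100*110/10100
#   IC_shrunk = log2(10.5/(E+0.5)); IC025 = IC_shrunk - 3.3/sqrt(10.5) - 2/10.5^1.5

test_that("PRR follows its defining ratio with distinct undefined states", {
  expect_equal(prr(10, 90, 100, 9900), 10)
  expect_equal(prr(5, 5, 5, 5), 1)
  expect_equal(prr(0, 10, 10, 100), 0)
  expect_identical(prr(3, 7, 0, 100), Inf)     # C = 0: never silently 0
  expect_true(is.na(prr(0, 0, 5, 5)))          # zero drug margin: undefined
})

test_that("ROR equals AD/BC, with Haldane correction only on zero cells", {
  expect_equal(ror(10, 90, 100, 9900), 11)
  expect_equal(ror(5, 5, 5, 5), 1)
  expect_true(is.na(ror(3, 0, 10, 1000)))
  expect_equal(ror(3, 0, 10, 1000, correction = "haldane"),
               3.5 * 1000.5 / (0.5 * 10.5))
  expect_equal(ror(3, 0, 10, 1000, correction = "haldane"), 667, tolerance = 1e-4)
  # correction leaves tables without zeros untouched
  expect_equal(ror(10, 90, 100, 9900, correction = "haldane"), 11)
})

test_that("the Woolf interval brackets the ROR symmetrically on log scale", {
  ci <- ror_ci(10, 90, 100, 9900)
  se <- sqrt(1 / 10 + 1 / 90 + 1 / 100 + 1 / 9900)
  z <- qnorm(0.975)
  expect_equal(ci$lower, exp(log(11) - z * se), tolerance = 1e-12)
  expect_equal(ci$upper, exp(log(11) + z * se), tolerance = 1e-12)
  expect_equal(ci$lower, 5.559585, tolerance = 1e-6)
  expect_equal(ci$upper, 21.764216, tolerance = 1e-6)

  # null table: interval contains 1, symmetric on the log scale
  ci2 <- ror_ci(100, 100, 100, 100)
  expect_lt(ci2$lower, 1); expect_gt(ci2$upper, 1)
  expect_equal(log(ci2$lower) + log(ci2$upper), 0, tolerance = 1e-12)

  # degenerate all-ones table: finite interval straddling 1
  ci3 <- ror_ci(1, 1, 1, 1)
  expect_true(is.finite(ci3$lower) && is.finite(ci3$upper))
  expect_lt(ci3$lower, 1); expect_gt(ci3$upper, 1)

  # interval ordering lower <= ROR <= upper on random tables
  tt <- random_tables(200, seed = 5)
  ci4 <- ror_ci(tt$A, tt$B, tt$C, tt$D)
  est <- ror(tt$A, tt$B, tt$C, tt$D)
  expect_true(all(ci4$lower <= est & est <= ci4$upper))
})

test_that("Woolf interval is consistent with a large-sample bootstrap", {
  # independent oracle: multinomial resampling of the reference-table cell
  # proportions in the large-count regime where the log-normal interval is
  # asymptotically exact (at A = 10 the bootstrap log-odds spread exceeds
  # the Woolf standard error by ~8%, which is the small-count bias the
  # interval knowingly ignores)
  set.seed(99)
  nb <- 1e5
  k <- 20
  cells <- stats::rmultinom(nb, 10100 * k, c(10, 90, 100, 9900) / 10100)
  boot <- (cells[1, ] * cells[4, ]) / (cells[2, ] * cells[3, ])
  q <- unname(stats::quantile(boot, c(0.025, 0.975)))
  ci <- ror_ci(10 * k, 90 * k, 100 * k, 9900 * k)
  expect_equal(ci$lower, q[1], tolerance = 0.05)
  expect_equal(ci$upper, q[2], tolerance = 0.05)
})

test_that("Pearson chi-squared matches its expected-counts form", {
  expect_equal(chi2_2x2(10, 90, 100, 9900), 74.44717, tolerance = 1e-5)
  expect_equal(chi2_2x2(1, 9, 10, 90), 0)       # perfectly proportional

  tt <- random_tables(1000, seed = 8)
  mine <- chi2_2x2(tt$A, tt$B, tt$C, tt$D)
  oe <- vapply(seq_len(nrow(tt)), function(i) {
    o <- matrix(as.numeric(tt[i, c("A", "B", "C", "D")]), 2, byrow = TRUE)
    e <- outer(rowSums(o), colSums(o)) / sum(o)
    sum((o - e)^2 / e)
  }, numeric(1))
  expect_equal(mine, oe, tolerance = 1e-12)

  # and the Yates-corrected form against R's own implementation
  idx <- sample(nrow(tt), 50)
  for (i in idx) {
    o <- matrix(as.numeric(tt[i, c("A", "B", "C", "D")]), 2, byrow = TRUE)
    expect_equal(chi2_2x2(o[1], o[1, 2], o[2, 1], o[2, 2], yates = TRUE),
                 unname(suppressWarnings(chisq.test(o)$statistic)),
                 tolerance = 1e-10)
    expect_equal(chi2_2x2(o[1], o[1, 2], o[2, 1], o[2, 2]),
                 unname(suppressWarnings(chisq.test(o, correct = FALSE)$statistic)),
                 tolerance = 1e-10)
  }
})

test_that("information component matches its observed/expected definitions", {
  expect_equal(ic(10, 90, 100, 9900, estimator = "raw"),
               log2(10 * 10100 / (100 * 110)))
  expect_equal(ic(10, 90, 100, 9900, estimator = "raw"), 3.199, tolerance = 1e-3)
  expect_equal(ic(1, 9, 9, 81, estimator = "raw"), 0)  # exact independence
  expect_equal(ic(10, 90, 100, 9900), 2.724, tolerance = 1e-3)
  expect_identical(ic(0, 10, 10, 100, estimator = "raw"), -Inf)
  # natural-log option
  expect_equal(ic(10, 90, 100, 9900, base = exp(1)),
               ic(10, 90, 100, 9900) * log(2))
})

test_that("IC025 closed form matches hand arithmetic and the MC posterior", {
  expect_equal(ic_lci95(10, 90, 100, 9900),
               ic(10, 90, 100, 9900) - 3.3 / sqrt(10.5) - 2 / 10.5^1.5)
  expect_equal(ic_lci95(10, 90, 100, 9900), 1.647, tolerance = 2e-3)

  set.seed(31)
  mc <- ic_lci95(10, 90, 100, 9900, method = "mc", draws = 1e6)
  expect_equal(mc, ic_lci95(10, 90, 100, 9900), tolerance = 0.05)

  # null coverage: large-count independence table has IC025 < 0
  expect_lt(ic_lci95(1000, 9000, 9000, 81000), 0)
})

test_that("IC025 is monotone increasing in A at fixed expected count", {
  lci <- vapply(c(3, 5, 10, 25, 60, 150),
                function(a) pvsignal:::.ic025_noren(a, E = 5), numeric(1))
  expect_true(all(diff(lci) > 0))
})

test_that("scale invariance and rare-event ROR/PRR agreement hold", {
  tt <- random_tables(200, seed = 13)
  k <- 7
  expect_equal(prr(tt$A * k, tt$B * k, tt$C * k, tt$D * k),
               prr(tt$A, tt$B, tt$C, tt$D))
  expect_equal(ror(tt$A * k, tt$B * k, tt$C * k, tt$D * k),
               ror(tt$A, tt$B, tt$C, tt$D))
  expect_equal(ic(tt$A * k, tt$B * k, tt$C * k, tt$D * k, estimator = "raw"),
               ic(tt$A, tt$B, tt$C, tt$D, estimator = "raw"))

  # exact identity ROR/PRR = [(A+B)/B] * [D/(C+D)]
  ratio <- ror(tt$A, tt$B, tt$C, tt$D) / prr(tt$A, tt$B, tt$C, tt$D)
  expect_equal(ratio, ((tt$A + tt$B) / tt$B) * (tt$D / (tt$C + tt$D)),
               tolerance = 1e-12)

  # rare events: the two indices agree within 10%
  rare <- data.frame(A = sample(1:20, 50, replace = TRUE),
                     B = sample(400:2000, 50, replace = TRUE),
                     C = sample(1:50, 50, replace = TRUE),
                     D = sample(2000:50000, 50, replace = TRUE))
  rare <- rare[rare$B / (rare$A + rare$B) >= 0.95 &
               rare$D / (rare$C + rare$D) >= 0.95, ]
  rel <- abs(ror(rare$A, rare$B, rare$C, rare$D) -
             prr(rare$A, rare$B, rare$C, rare$D)) /
         prr(rare$A, rare$B, rare$C, rare$D)
  expect_true(all(rel <= 0.1))

  # shrinkage converges to the raw IC as counts grow at fixed ratios
  expect_equal(ic(10 * 1e4, 90 * 1e4, 100 * 1e4, 9900 * 1e4),
               ic(10, 90, 100, 9900, estimator = "raw"), tolerance = 1e-3)
})

test_that("the tri-criteria rule reproduces published star patterns", {
  crit <- signal_criteria()
  # control-drug extrapyramidal statistics: flagged by all three indices
  f1 <- signal_flags(A = 30, prr = 25.39, ror_ = 27.72, chi2 = 100,
                     ic_lci = 2.70, crit)
  expect_true(f1$definitive_signal)
  # strong statistics but A = 2 < 3: no signal
  f2 <- signal_flags(A = 2, prr = 55.68, ror_ = 56.28, chi2 = 100,
                     ic_lci = 2.22, crit)
  expect_false(f2$prr_signal)
  expect_false(f2$definitive_signal)
  expect_true(f2$ic_signal)   # the IC criterion alone does not gate on A
  # null statistics: nothing fires
  f3 <- signal_flags(A = 50, prr = 1, ror_ = 1, chi2 = 0, ic_lci = -1, crit)
  expect_false(any(unlist(f3)))
  # thresholds are >= comparisons on unrounded values
  f4 <- signal_flags(A = 3, prr = 2, ror_ = 2, chi2 = 4, ic_lci = 0, crit)
  expect_true(f4$definitive_signal)
  # undefined statistics fail their criterion
  f5 <- signal_flags(A = 5, prr = Inf, ror_ = NA_real_, chi2 = 10,
                     ic_lci = 0.5, crit)
  expect_false(f5$prr_signal)
  expect_false(f5$ror_signal)
  expect_true(f5$ic_signal)
})
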