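#' Proportional reporting ratio
#'
#' PRR = `[A/(A+B)] / [C/(C+D)]`: the proportion of the target drug's units
#' that are the target event, relative to the same proportion among all
#' other drugs.
#'
#' All statistic functions in this family are vectorised over the four
#' cells.  `C = 0` with `A >= 1` yields `Inf` (infinite disproportionality,
#' signalled distinctly — never silently 0); a zero `A+B` or `C+D` margin
#' yields `NA`.  Non-finite values fail every signal criterion downstream.
#'
#' @param A,B,C,D cells of the 2x2 table(s): target drug & target event,
#'   target drug & other events, other drugs & target event, remainder.
#' @return numeric vector of PRR values.
#' @export
prr <- function(A, B, C, D) {
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)
  out <- (A / (A + B)) / (C / (C + D))
  out[(A + B) == 0 | (C + D) == 0] <- NA_real_
  out[A == 0 & (A + B) > 0 & (C + D) > 0] <- 0
  out[A > 0 & C == 0 & (A + B) > 0 & (C + D) > 0] <- Inf
  out
}

#' Reporting odds ratio
#'
#' ROR = `(A/B) / (C/D) = AD/BC`.  With `correction = "none"` a zero in
#' `B`, `C` or `D` yields `NA` (undefined, signalled distinctly).  With
#' `correction = "haldane"` the Haldane-Anscombe correction
#' `(A+0.5)(D+0.5) / ((B+0.5)(C+0.5))` is applied, and only to tables with
#' at least one zero cell.
#'
#' @inheritParams prr
#' @param correction `"none"` (default) or `"haldane"`.
#' @return numeric vector of ROR values.
#' @export
ror <- function(A, B, C, D, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)
  out <- (A * D) / (B * C)
  zero <- A == 0 | B == 0 | C == 0 | D == 0
  if (correction == "haldane") {
    out[zero] <- ((A + 0.5) * (D + 0.5) / ((B + 0.5) * (C + 0.5)))[zero]
  } else {
    out[B == 0 | C == 0 | D == 0] <- NA_real_
  }
  out
}

#' Woolf 95% confidence interval for the reporting odds ratio
#'
#' `exp(ln ROR -+ z * sqrt(1/A + 1/B + 1/C + 1/D))`, the standard
#' log-normal (Woolf) interval.  Under the Haldane correction the corrected
#' cells enter both the point estimate and the variance for tables with a
#' zero cell.
#'
#' @inheritParams ror
#' @param conf_level confidence level (default 0.95).
#' @return list with numeric vectors `lower` and `upper`.
#' @export
ror_ci <- function(A, B, C, D, correction = c("none", "haldane"),
                   conf_level = 0.95) {
  correction <- match.arg(correction)
  est <- ror(A, B, C, D, correction)
  zero <- A == 0 | B == 0 | C == 0 | D == 0
  a <- A; b <- B; cc <- C; d <- D
  if (correction == "haldane") {
    a[zero] <- A[zero] + 0.5; b[zero] <- B[zero] + 0.5
    cc[zero] <- C[zero] + 0.5; d[zero] <- D[zero] + 0.5
  }
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(lower = exp(log(est) - z * se), upper = exp(log(est) + z * se))
}

#' Pearson chi-squared statistic for a 2x2 table
#'
#' `N (AD - BC)^2 / [(A+B)(C+D)(A+C)(B+D)]`, algebraically identical to
#' `sum((O - E)^2 / E)` over the four cells.  With `yates = TRUE` the
#' continuity-corrected form `N (|AD - BC| - N/2)^2 / (...)` is used,
#' floored at 0.  A zero margin yields `NA`.
#'
#' @inheritParams prr
#' @param yates apply the Yates continuity correction (default `FALSE`).
#' @return numeric vector of chi-squared values.
#' @export
chi2_2x2 <- function(A, B, C, D, yates = FALSE) {
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)
  N <- A + B + C + D
  denom <- (A + B) * (C + D) * (A + C) * (B + D)
  num <- if (yates) N * pmax(abs(A * D - B * C) - N / 2, 0)^2
         else N * (A * D - B * C)^2
  out <- num / denom
  out[denom == 0] <- NA_real_
  out
}

#' Information component
#'
#' The BCPNN information component measures, in bits, how much more often a
#' drug-event pair is reported than expected under independence:
#' `IC = log2[ P(drug, event) / (P(drug) P(event)) ]`.
#'
#' `estimator = "raw"` gives `log2[A N / ((A+B)(A+C))]` (`-Inf` when
#' `A = 0`, signalled distinctly).  `estimator = "shrinkage"` (default)
#' applies the 0.5-shrinkage observed/expected form
#' `log2[(A + 0.5) / (E + 0.5)]` with expected count
#' `E = (A+B)(A+C)/N`, defined for every table and shrunk towards 0 for
#' sparse cells.
#'
#' @inheritParams prr
#' @param estimator `"shrinkage"` (default) or `"raw"`.
#' @param base logarithm base; 2 (bits, the BCPNN convention) by default,
#'   set `exp(1)` for nats.
#' @return numeric vector of IC values.
#' @export
ic <- function(A, B, C, D, estimator = c("shrinkage", "raw"), base = 2) {
  estimator <- match.arg(estimator)
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)
  N <- A + B + C + D
  E <- (A + B) * (A + C) / N
  if (estimator == "raw") {
    out <- log(A / E, base = base)
    out[A == 0] <- -Inf
  } else {
    out <- log((A + 0.5) / (E + 0.5), base = base)
  }
  out
}

## Noren closed-form approximation to the 2.5th percentile of the IC
## posterior, as a function of the observed count and expected count only.
.ic025_noren <- function(A, E) {
  log2((A + 0.5) / (E + 0.5)) - 3.3 * (A + 0.5)^-0.5 - 2 * (A + 0.5)^-1.5
}

#' Lower 95% credible bound of the information component
#'
#' The signal criterion for the IC is that the lower end of its 95%
#' interval (IC025) is at or above 0.  Two constructions are provided:
#'
#' * `"noren"` (default): the closed-form approximation
#'   `IC - 3.3 (A+0.5)^{-1/2} - 2 (A+0.5)^{-3/2}` around the 0.5-shrinkage
#'   observed/expected estimator.
#' * `"mc"`: the 2.5th percentile of `log2` of draws from the gamma
#'   posterior of the observed/expected ratio, shape `A + 0.5` and rate
#'   `E + 0.5`; the stochastic cross-check of the closed form.
#'
#' @inheritParams prr
#' @param method `"noren"` or `"mc"`.
#' @param draws Monte-Carlo draw count per table (`method = "mc"`).
#' @return numeric vector of IC025 values in bits.
#' @export
ic_lci95 <- function(A, B, C, D, method = c("noren", "mc"), draws = 1e5) {
  method <- match.arg(method)
  A <- as.numeric(A); B <- as.numeric(B)
  C <- as.numeric(C); D <- as.numeric(D)
  N <- A + B + C + D
  E <- (A + B) * (A + C) / N
  if (method == "noren") return(.ic025_noren(A, E))
  vapply(seq_along(A), function(i) {
    stats::quantile(log2(stats::rgamma(draws, shape = A[i] + 0.5,
                                       rate = E[i] + 0.5)),
                    probs = 0.025, names = FALSE)
  }, numeric(1))
}

#' Signal detection criteria
#'
#' Thresholds of the tri-criteria rule: the PRR criterion requires
#' `PRR >= prr_min`, `chi2 >= chi2_min` and `A >= min_A`; the ROR criterion
#' is analogous with `ror_min`; the IC criterion requires
#' `IC025 >= ic_lci_min`.  A pair flagged by all three is a definitive
#' signal.
#'
#' @param prr_min,ror_min disproportionality thresholds (default 2).
#' @param chi2_min chi-squared threshold (default 4).
#' @param min_A minimum number of reports in cell A (default 3).
#' @param ic_lci_min IC025 threshold in bits (default 0).
#' @return a list of class `signal_criteria`.
#' @export
signal_criteria <- function(prr_min = 2, ror_min = 2, chi2_min = 4,
                            min_A = 3L, ic_lci_min = 0) {
  stopifnot(is.finite(prr_min), is.finite(ror_min), is.finite(chi2_min),
            is.finite(ic_lci_min), min_A >= 1)
  structure(list(prr_min = prr_min, ror_min = ror_min, chi2_min = chi2_min,
                 min_A = as.integer(min_A), ic_lci_min = ic_lci_min),
            class = "signal_criteria")
}

#' Apply the tri-criteria signal rule
#'
#' Comparisons use `>=` on the unrounded statistics, with no epsilon.
#' Undefined (`NA`) or non-finite statistics fail their criterion.
#'
#' @param A cell-A counts.
#' @param prr,ror_,chi2,ic_lci statistic vectors (as computed by [prr()],
#'   [ror()], [chi2_2x2()], [ic_lci95()]).
#' @param criteria a [signal_criteria()] object.
#' @return data frame with logical columns `prr_signal`, `ror_signal`,
#'   `ic_signal`, `definitive_signal`.
#' @export
signal_flags <- function(A, prr, ror_, chi2, ic_lci,
                         criteria = signal_criteria()) {
  stopifnot(inherits(criteria, "signal_criteria"))
  ok <- function(x, thr) !is.na(x) & is.finite(x) & x >= thr
  chi_ok <- ok(chi2, criteria$chi2_min)
  a_ok <- A >= criteria$min_A
  prr_signal <- ok(prr, criteria$prr_min) & chi_ok & a_ok
  ror_signal <- ok(ror_, criteria$ror_min) & chi_ok & a_ok
  ic_signal <- ok(ic_lci, criteria$ic_lci_min)
  data.frame(prr_signal = prr_signal, ror_signal = ror_signal,
             ic_signal = ic_signal,
             definitive_signal = prr_signal & ror_signal & ic_signal)
}
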