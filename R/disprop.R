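#' Fit a disproportionality analysis to spontaneous report data
#'
#' The central model-fitting function of the package.  Expands the dataset
#' into drug-event units, builds the 2x2 contingency table of every
#' observed pair, computes the three disproportionality indices -- PRR,
#' ROR with its Woolf 95% confidence interval, and the BCPNN information
#' component with its 95% lower credible bound -- together with the Pearson
#' chi-squared statistic, and applies the tri-criteria signal rule.
#'
#' @param data an `srs_data` object (normally the output of
#'   [run_filter_cascade()]), a unit data frame from [expand_pairs()], or a
#'   `contingency_set` from [contingency_tables()].
#' @param criteria a [signal_criteria()] object.
#' @param counting_unit `"pair"` (distinct (report, drug, event) triples,
#'   default) or `"report"`; ignored when `data` is already a
#'   `contingency_set`.
#' @param ic_method IC interval construction, `"noren"` (closed form,
#'   default) or `"mc"` (gamma-posterior Monte Carlo).
#' @param ic_draws draws per table for `ic_method = "mc"`.
#' @param ror_correction `"none"` (default) or `"haldane"`; under
#'   `"none"`, tables with zero cells carry `NA` RORs that fail the ROR
#'   criterion.
#' @param chi2_yates apply the Yates continuity correction (default
#'   `FALSE`, plain Pearson).
#' @param conf_level confidence level for the ROR interval.
#'
#' @return an object of class `disprop`: a list with elements `results`
#'   (one row per pair, ordered by (drug, event), with cells, statistics at
#'   full precision, and per-criterion flags), `criteria`, `counting_unit`,
#'   `N`, and `options`.
#'
#' @examples
#' cfg <- sim_config(n_reports = 2000,
#'                   drugs = c(drug_a = 1, drug_b = 1),
#'                   events = c(nausea = 0.05, rash = 0.05, tremor = 0.05),
#'                   signal_pairs = data.frame(drug = "drug_a",
#'                                             event = "tremor",
#'                                             rate_ratio = 8),
#'                   seed = 1)
#' fit <- disprop(run_filter_cascade(simulate_srs(cfg)))
#' summary(fit)
#' @export
disprop <- function(data, criteria = signal_criteria(),
                    counting_unit = c("pair", "report"),
                    ic_method = c("noren", "mc"), ic_draws = 1e5,
                    ror_correction = c("none", "haldane"),
                    chi2_yates = FALSE, conf_level = 0.95) {
  counting_unit <- match.arg(counting_unit)
  ic_method <- match.arg(ic_method)
  ror_correction <- match.arg(ror_correction)
  stopifnot(inherits(criteria, "signal_criteria"))

  tab <- if (inherits(data, "contingency_set")) data
         else contingency_tables(data, counting_unit)
  if (inherits(data, "contingency_set"))
    counting_unit <- attr(data, "counting_unit")

  res <- as.data.frame(tab)
  class(res) <- "data.frame"
  A <- res$A; B <- res$B; C <- res$C; D <- res$D
  res$prr <- prr(A, B, C, D)
  res$ror <- ror(A, B, C, D, correction = ror_correction)
  ci <- ror_ci(A, B, C, D, correction = ror_correction,
               conf_level = conf_level)
  res$ror_lower <- ci$lower
  res$ror_upper <- ci$upper
  res$chi2 <- chi2_2x2(A, B, C, D, yates = chi2_yates)
  res$ic <- ic(A, B, C, D, estimator = "shrinkage")
  res$ic_lci95 <- ic_lci95(A, B, C, D, method = ic_method, draws = ic_draws)
  flags <- signal_flags(A, res$prr, res$ror, res$chi2, res$ic_lci95,
                        criteria)
  res <- cbind(res, flags)
  res <- res[order(res$drug, res$event), , drop = FALSE]
  rownames(res) <- NULL

  structure(list(results = res, criteria = criteria,
                 counting_unit = counting_unit, N = attr(tab, "N"),
                 options = list(ic_method = ic_method,
                                ror_correction = ror_correction,
                                chi2_yates = chi2_yates,
                                conf_level = conf_level)),
            class = "disprop")
}

#' @export
print.disprop <- function(x, ...) {
  r <- x$results
  cat("Disproportionality analysis (", x$counting_unit, "-level counting)\n",
      sep = "")
  cat("  units (N):         ", x$N, "\n")
  cat("  drug-event pairs:  ", nrow(r), "\n")
  cat("  definitive signals:", sum(r$definitive_signal), "\n")
  invisible(x)
}

#' Summarise a disproportionality analysis
#'
#' @param object a `disprop` object.
#' @param ... unused.
#' @return an object of class `summary.disprop` listing per-criterion
#'   signal counts and the definitive signal rows.
#' @export
summary.disprop <- function(object, ...) {
  r <- object$results
  structure(list(n_pairs = nrow(r), N = object$N,
                 counting_unit = object$counting_unit,
                 n_prr = sum(r$prr_signal), n_ror = sum(r$ror_signal),
                 n_ic = sum(r$ic_signal),
                 n_definitive = sum(r$definitive_signal),
                 signals = r[r$definitive_signal, , drop = FALSE]),
            class = "summary.disprop")
}

#' @export
print.summary.disprop <- function(x, ...) {
  cat("Disproportionality analysis summary\n")
  cat(sprintf("  %d pairs over %d %s-level units\n", x$n_pairs, x$N,
              x$counting_unit))
  cat(sprintf("  criterion hits: PRR %d | ROR %d | IC %d\n",
              x$n_prr, x$n_ror, x$n_ic))
  cat(sprintf("  definitive signals: %d\n", x$n_definitive))
  if (nrow(x$signals)) {
    s <- x$signals
    cat("\n  drug             event                A    PRR    ROR  IC025\n")
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-16s %-18s %4d %6.2f %6.2f %6.2f\n",
                  s$drug[i], s$event[i], s$A[i], s$prr[i], s$ror[i],
                  s$ic_lci95[i]))
  }
  invisible(x)
}

#' Extract the disproportionality statistics
#'
#' @param object a `disprop` object.
#' @param ... unused.
#' @return numeric matrix (pairs x statistics) with rows named
#'   `drug:event` and columns `A`, `prr`, `ror`, `chi2`, `ic`, `ic_lci95`.
#' @export
coef.disprop <- function(object, ...) {
  r <- object$results
  m <- as.matrix(r[, c("A", "prr", "ror", "chi2", "ic", "ic_lci95")])
  rownames(m) <- paste(r$drug, r$event, sep = ":")
  m
}

#' @export
as.data.frame.disprop <- function(x, row.names = NULL, optional = FALSE, ...) {
  x$results
}

#' Heatmap of the signal detection results for one drug
#'
#' Draws the [heatmap_matrix()] grid (events x indices) with detected
#' signals marked "V", in the style of SRS signal-detection heatmaps.
#'
#' @param x a `disprop` object.
#' @param drug drug code to display.
#' @param ... passed to [graphics::image()].
#' @return the plotted matrix, invisibly.
#' @export
plot.disprop <- function(x, drug, ...) {
  m <- heatmap_matrix(x, drug)
  vals <- log10(pmax(m, 1e-3))
  nr <- nrow(m); nc <- ncol(m)
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(x = seq_len(nc), y = seq_len(nr), z = t(vals[nr:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(25, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", main = drug, ...)
  graphics::axis(1, at = seq_len(nc), labels = colnames(m), tick = FALSE)
  graphics::axis(2, at = seq_len(nr), labels = rev(rownames(m)), las = 2,
                 tick = FALSE, cex.axis = 0.8)
  sig <- attr(m, "signal")
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      if (isTRUE(sig[i, j]))
        graphics::text(j, nr - i + 1, "V", font = 2)
  invisible(m)
}
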