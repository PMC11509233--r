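# pvsignal

Disproportionality-based safety signal detection for spontaneous adverse
event reports.

## What it is for

Spontaneous reporting systems (SRS) — KAERS, FAERS, VigiBase and their
kin — collect voluntary reports of suspected adverse drug events (ADEs)
with no exposure denominator. Pharmacovigilance teams screen such data by
**disproportionality analysis**: for every drug–event pair, a 2×2 table

|                 | target event | all other events |
|-----------------|--------------|------------------|
| target drug     | A            | B                |
| all other drugs | C            | D                |

is scored with three indices,

- **PRR** = [A/(A+B)] / [C/(C+D)]  — signal when PRR ≥ 2, χ² ≥ 4, A ≥ 3,
- **ROR** = AD/BC with a Woolf 95% CI — signal when ROR ≥ 2, χ² ≥ 4, A ≥ 3,
- **IC** = log₂[P(drug, event) / (P(drug)·P(event))] with the BCPNN
  0.5-shrinkage estimator — signal when the 95% lower credible bound
  (IC025) ≥ 0,

and a pair flagged by **all three** criteria is a *definitive signal*.
pvsignal implements the full pipeline for analysts working with
report-level SRS extracts (or, lacking access to one, with its synthetic
generator): reading long-format report tables, the standard cleaning
cascade (masked-code removal, missing-value exclusion, study-window
restriction, case-series deduplication, minimum-case inclusion),
contingency construction, the three indices with explicit handling of
zero cells, demographic summaries, per-drug signal tables with
label-expectedness annotation, positive-control validation, and heatmap
matrices.

## Worked example

Simulate a reporting system with a known positive control — an
antidopaminergic antiemetic paired with an extrapyramidal-disorder event
at reporting-rate ratio 12 over a null background — then clean, fit and
validate:

```r
library(pvsignal)

cfg   <- positive_control_scenario(n_reports = 20000, seed = 11)
ds    <- simulate_srs(cfg)            # 20994 reports (duplicates included)
clean <- run_filter_cascade(ds)       # masked / missing / window / dedup / min-cases
fit   <- disprop(clean)               # PRR, ROR + CI, chi^2, IC, IC025, flags
summary(fit)
```

```
Disproportionality analysis summary
  100 pairs over 21463 pair-level units
  criterion hits: PRR 1 | ROR 1 | IC 8
  definitive signals: 1

  drug             event                A    PRR    ROR  IC025
  metoclopramide   extrapyramidal_disorder 1802   8.15  12.81   1.61
```

Of the 100 drug–event pairs, only the embedded control association passes
all three criteria: it was reported 1802 times (cell A), about 8 times as
often as its share elsewhere in the data would predict (PRR 8.15), with an
IC whose lower credible bound (1.61 bits) sits far above 0. The IC
criterion alone fires on a handful of additional pairs — it carries no
χ²/case-count gate — which is exactly why the conjunction rule is used.

```r
validate_positive_control(fit, "metoclopramide", "extrapyramidal_disorder")
#> Positive control metoclopramide / extrapyramidal_disorder: PASS
#>   A = 1802, PRR = 8.15, ROR = 12.81, IC025 = 1.61
```

Per-drug output surfaces:

```r
build_signal_table(fit, "metoclopramide")   # rendered table, expectedness joins
heatmap_matrix(fit, "metoclopramide")       # events x (PRR, ROR, IC025) grid
plot(fit, "metoclopramide")                 # heatmap with signals marked "V"
summarize_demographics(clean)               # counts + half-up percentages
```

Real extracts enter through `read_srs_reports()` (long TSV/CSV, one row
per report–drug–event occurrence; columns `report_id`, `series_id`,
`sequence_no`, `receipt_date`, `drug`, `event`, `sex`, `age_years`,
`causality`, `seriousness`, `reporter_type`, `report_type`,
`disposition`, `masked`) and label-expectedness references through
`read_expectedness()` (3-column `drug`, `event`, `source` with sources
MFDS/FDA).

See `vignettes/signal-detection-methods.Rmd` for the model, the design
decisions (counting units, tie-breaking, denominators, IC interval
construction) and the generator's assumptions and limits.

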