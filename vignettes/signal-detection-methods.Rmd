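---
title: "Disproportionality-based signal detection: models, choices and limits"
author: "pvsignal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality-based signal detection: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems (SRS) such as KAERS, FAERS or VigiBase collect
voluntary post-marketing reports of suspected adverse drug events (ADEs).
They have no denominator of exposed patients, so absolute risks cannot be
estimated; instead, *disproportionality analysis* asks whether a drug-event
pair is reported more often than the background of all other drugs and
events would predict. For each pair, the units of analysis are classified
into a 2x2 table:

|                 | target event | all other events |
|-----------------|--------------|------------------|
| target drug     | A            | B                |
| all other drugs | C            | D                |

with `N = A + B + C + D`. pvsignal computes three standard indices on each
table and combines them into a conservative tri-criteria rule.

## The indices

* **Proportional reporting ratio.**
  `PRR = [A/(A+B)] / [C/(C+D)]` — the event's share of the drug's reports
  relative to its share elsewhere. Signal criterion: `PRR >= 2` together
  with Pearson `chi^2 >= 4` and `A >= 3`.
* **Reporting odds ratio.**
  `ROR = (A/B)/(C/D) = AD/BC`, with a Woolf (log-normal) 95% confidence
  interval, `exp(ln ROR -+ z_{0.975} sqrt(1/A + 1/B + 1/C + 1/D))`.
  Signal criterion: `ROR >= 2`, `chi^2 >= 4`, `A >= 3`. For rare events
  (`B >> A`, `D >> C`) the exact identity
  `ROR/PRR = [(A+B)/B] [D/(C+D)]` keeps the two indices within 10% of one
  another.
* **Information component.**
  The BCPNN information component
  `IC = log2[ P(drug, event) / (P(drug) P(event)) ]`, estimated with the
  0.5-shrinkage observed/expected form `log2[(A + 0.5)/(E + 0.5)]`,
  `E = (A+B)(A+C)/N`, which is defined for every table and pulls sparse
  cells towards 0. Signal criterion: the lower end of the 95% credible
  interval (IC025) at or above 0.

A pair flagged by all three criteria simultaneously is a **definitive
signal**. The conjunction is deliberately conservative: under null
simulations with moderate-to-large cell counts the definitive-signal rate is
far below 5% (the suite measures it at 0 out of 1000 null pairs).

### The IC025 construction

The posterior of the observed/expected ratio under the BCPNN shrinkage
prior is well approximated by a gamma distribution with shape `A + 0.5` and
rate `E + 0.5`. Two constructions of its 2.5th percentile are implemented:

* the **closed form** `IC - 3.3 (A+0.5)^{-1/2} - 2 (A+0.5)^{-3/2}` (the
  default), and
* a **Monte-Carlo** percentile of `log2` gamma draws (`ic_lci95(...,
  method = "mc")`).

The analytic gap between the two depends only on `A` (the `E` dependence
cancels exactly, since scaling a gamma's rate shifts every log-quantile by
the same constant). It peaks just below 0.05 bits around `A ≈ 16` and
shrinks in both directions. The cross-validation test therefore tiers its
draw counts — 4x10^7 draws for tables with `A <= 100`, 2x10^6 otherwise —
so that Monte-Carlo noise (standard error about 0.0006 bits at 4x10^7
draws) stays an order of magnitude below the remaining analytic margin.
For `A < 5` the closed form is a cruder bound and the two constructions
should not be expected to agree tightly; the IC criterion there leans on
the shrinkage estimator itself.

### Undefined statistics

Zero cells are carried as explicit undefined states, never imputed:
`PRR = Inf` when `C = 0` (infinite disproportionality, reported distinctly,
never silently 0), `ROR = NA` when `B`, `C` or `D` is 0, `chi^2 = NA` on a
zero margin, raw `IC = -Inf` when `A = 0`. Every non-finite statistic fails
its criterion, so an undefined index can never *create* a signal. The
opt-in Haldane-Anscombe correction (`ror_correction = "haldane"`) adds 0.5
to all cells of a zero-cell table for users who prefer a finite estimate;
it touches only tables with zeros. Threshold comparisons use `>=` on
unrounded values with no epsilon; the 2-decimal rendering in
`build_signal_table()` is display only, and flags are always derived from
the unrounded statistics (so a rendered value of, say, 2.00 may carry no
flag if the underlying value is 1.9996).

## Cleaning cascade

`run_filter_cascade()` applies, in order: masked-record removal
(the "MSK" anonymisation code marks products with two or fewer
manufacturers), missing-value exclusion, study-window restriction
(inclusive at both ends; default 2013-01-01 to 2022-12-31),
case-series deduplication, and the minimum-case rule (drugs in fewer than
3 distinct reports are excluded). Design choices that were genuinely open:

* **Stage order.** The window filter runs *before* deduplication so that
  "last report of a series" is judged within the study period — a
  successor filed after the window closes should not evict an in-window
  report it cannot represent.
* **"Last report" ordering.** No ordering key is canonical across SRS
  extracts; pvsignal uses the lexicographic maximum of
  (`sequence_no`, `receipt_date`, `report_id`), which gives a unique,
  deterministic survivor under any tie pattern (verified by exhaustive
  permutation tests).
* **Missing-value policy.** Which fields were "required" varies by study;
  the default excludes only reports without a causality assessment, and
  `filter_config(required_fields = ...)` widens it. Demographic tables in
  published SRS studies typically show per-field `n`s smaller than the
  total, indicating that some missingness survives filtering — hence the
  configurability.
* **"Cases" for the minimum-case rule** are distinct post-deduplication
  reports, not drug-event rows.

Each stage appends a provenance entry (`step`, `n_in`, `n_out`,
`n_removed`) with `n_in = n_out + n_removed` enforced; the cascade is
idempotent and subset-monotone.

## Counting units

Published SRS analyses rarely state whether the 2x2 margins count
drug-event pairs or whole reports. pvsignal implements both:

* `counting_unit = "pair"` (default): one unit per distinct
  (report, drug, event) triple — the dominant convention;
* `counting_unit = "report"`: each report counts once per cell under
  any-mention semantics.

For single-drug reports and rare events the two converge. The default is
the pair unit because report counts per event are what per-drug signal
tables print, while reports may carry several drugs and events.

## The synthetic reporting system

`simulate_srs()` draws datasets with known ground truth so every stage is
testable without access to a licensed SRS extract. The generative model:

1. each report draws its drug count from a truncated geometric
   (minimum 1, configurable mean) and its drugs by exposure weight without
   replacement;
2. each event enters independently with probability
   `baseline_rate(e) * max over the report's drugs of rate_ratio(d, e)`;
   reports with no event are redrawn (an ADE report without an event is
   not a report);
3. duplicates are exact clones with incremented `sequence_no` in the same
   series; masking, missingness and demographics are applied afterwards.

A single seeded RNG stream with a fixed, vectorised draw order makes
generation byte-reproducible per seed.

**What the generator emulates and what it does not.** It reproduces the
*statistical* structure the disproportionality model assumes —
multiplicative reporting-rate signals over an independent background, plus
the administrative noise (duplicates, masking, missingness) the cascade
must remove. It does not emulate reporting trends over time (Weber
effects), drug-drug interactions, correlated event clusters, terminology
hierarchies, or the real (unpublished) marginal distributions of
drugs/events per report — defaults there are documented guesses
(`drugs_per_report_mean = 1.2`, twenty events at baseline 0.02 in the
packaged scenarios). Passing recovery tests therefore show that the
machinery is correct under its own assumptions, not that real-data signals
are as clean.

**Attenuation under the at-least-one-event constraint.** Conditioning
every report on carrying an event inflates all inclusion probabilities by
a per-report factor, and inflates the *denominator* events of a
signal-carrying drug along with the signal event. At the packaged recovery
conditions (5 drugs, 20 events, baseline 0.02, rate ratio 5) the expected
pair-unit PRR is about 4.17 rather than 5 — a ~17% attenuation that is a
property of the design, not an estimator bias; the recovery suite asserts
estimates within 20% of the configured ratio accordingly.

**Packaged scenarios.**
`positive_control_scenario()` embeds one strong control association — an
antidopaminergic antiemetic (metoclopramide) with an
extrapyramidal-disorder event at rate ratio 12 — among null background
pairs, mirroring the standard practice of validating SRS machinery on an
association known to be real. `recovery_scenario()` is the clean
calibration design above (no duplicates/masking/missingness, one drug per
report) so that recovery isolates the statistics.

## Problem sizes and numerical choices

The validation suite uses: 20 replicate datasets of 20 000 reports for
parameter recovery; one 50 000-report, 50-drug dataset giving 1000 null
pairs with expected cell counts near 60 for calibration; 1000 random 2x2
tables for the formula oracles (relative error < 1e-10 against
expected-count and odds-identity forms, and against `chisq.test`); and 100
random tables for the IC025 cross-validation with the tiered draw counts
described above. These sizes put Monte-Carlo noise well below every
asserted margin while keeping a full run in a few minutes.

Half-up rounding (`round_half_up()`) is used for all rendered percentages
(1 decimal) and statistics (2 decimals), matching the rounding convention
of published SRS tables rather than R's banker's rounding.

Demographic summaries default to the *mixed* denominator policy observed
in published SRS demographic tables: sex and age percentages are over
reports with the field recorded, while causality and administrative fields
are over the total report count (so causality categories need their
missing row displayed to sum to 100%). A consistent
(`denominators = "known"`) mode is available.

## Known limitations

* Crude (unstratified) disproportionality only — no age/sex adjustment, no
  EBGM/MGPS, no multiple-testing correction, by design.
* Disproportionality quantifies reporting behaviour, not risk; a
  definitive signal is a hypothesis for pharmacoepidemiologic follow-up,
  never a causal claim.
* Label-expectedness annotation relies on user-supplied reference lists;
  the package ships no label database.
* Codes are opaque normalized strings; no ATC/WHO-ART hierarchy is
  modelled, so related preferred terms are independent events to the
  statistics.
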