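---
title: "Disproportionality signal detection on spontaneous adverse-event reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on spontaneous adverse-event reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous-report databases such as FAERS collect voluntary reports of
suspected drug adverse events. They have no denominator — nobody knows how
many patients took each drug — so incidence cannot be estimated. What can
be asked is whether a drug–event pair is reported *disproportionally*
often compared with the database background. `faersignal` implements that
analysis as a pipeline: read the quarterly multi-table report files,
restrict events to one MedDRA system organ class (SOC), remove duplicate
submissions, keep reports where the drug was the primary suspect (PS),
and score every drug–event pair with the reporting odds ratio (ROR) and
proportional reporting ratio (PRR). The worked example throughout the
package is cardiac disorders reported for the five triazole antifungal
agents (fluconazole, voriconazole, itraconazole, posaconazole,
isavuconazole).

## Data model and screening funnel

A *case* is one (report, drug, preferred term) triple: a report listing
two cardiac PTs for the same drug contributes two cases, because
disproportionality is scored per drug–PT pair. Screening proceeds in the
order extract → SOC restriction → deduplication → PS filter, and the
per-stage counts are returned as an audit funnel; each stage only removes
rows, so the funnel is monotone.

**Deduplication.** Two case rows are duplicates when they agree on eight
fields: adverse event PT, report ID, receive date, drug, indication, sex,
reporter country and age. Two conventions were genuinely open and are
resolved as follows. Missing equals missing — two reports that both lack
an age can still be duplicates; treating missing as a wildcard would
over-delete in a database where these fields are frequently blank. The
surviving row is the earliest-loaded one; nothing in the source material
dictates a survivor, and a stable rule makes runs reproducible.

**Drug-name normalization.** Raw names are case-folded and matched against
a synonym table: exact match first, then the longest token prefix
(`"VFEND 200MG TAB"` → `vfend` → voriconazole). No edit-distance matching
is attempted; deterministic matching is auditable, and the synonym table
is the right place to encode known variants.

**Age.** All ages are converted to years (months / 12, days / 365.25) at
load. Records with unparseable dates or ages, negative ages, non-positive
doses, blank keys, or report IDs absent from the demographics table are
quarantined with a reason — accepted + quarantined always equals the input
row count, so nothing is silently dropped.

## The statistics

For a drug–event pair the 2×2 table against the whole analysis universe is

|            | target event | other events |
|------------|--------------|--------------|
| target drug | a | b |
| other drugs | c | d |

where the universe is every deduplicated PS case row for *all* drugs (the
background must contain non-study drugs and non-target events). A drug's
total (`a + b`) counts distinct (report, drug) pairs, so a report with
several non-target events still counts once toward its drug's total.

$$\mathrm{ROR} = \frac{a/b}{c/d}, \qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d}\Big)$$

$$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}, \qquad
\mathrm{CI}_{95} = \exp\!\Big(\ln \mathrm{PRR} \pm 1.96
\sqrt{\tfrac1a - \tfrac1{a+b} + \tfrac1c - \tfrac1{c+d}}\Big)$$

The two statistics fail differently at zero cells, which is why they are
used together: the ROR cannot be computed when `b` or `c` is zero, while
the PRR is still computable at `c = 0` (infinite, flagged) and only dies
at `a = 0`. By default no continuity correction is applied — undefined
results are flagged with a reason rather than papered over — and the
Haldane–Anscombe 0.5 correction is available behind an explicit argument.
The z value is fixed at 1.96 (a 95% interval).

**Signal criteria.** A pair is a signal when all of: reports `a ≥ 3`, ROR
lower 95% bound `> 1`, and `PRR ≥ 2` with Yates-corrected `χ² ≥ 4`. These
are the canonical published dual criteria; all four thresholds are
configurable through `signal_criteria()`. The χ² is computed with
`stats::chisq.test()`, Yates-corrected for the criterion (the classic
form) with the uncorrected variant reported alongside so the choice is
never hidden. An undefined statistic fails its criterion. When replaying
a published table that prints ROR/PRR and CIs but no χ², the χ² gate is
disabled (`use_chi2 = FALSE`); every printed row's PRR CI excludes 1 by a
wide margin, so the gate is not the binding constraint there. No
multiple-testing adjustment is applied: the criteria themselves play that
conservative-filter role in pharmacovigilance practice, and the suite
verifies that under a global null the flag rate stays below 5%.

## Descriptive conventions

* **One outcome per report.** When a report carries several outcome codes
  it is assigned a single category by severity priority death >
  life-threatening > hospitalization > disability > congenital anomaly >
  other (configurable). Published outcome rows sum to report totals, which
  implies single assignment; the priority order is the standard
  convention, and with it a report is "serious" if *any* of its codes is
  in the serious set.
* **Regions.** Countries are reported as United States, Japan, China,
  France, United Kingdom, Germany, Canada, and "Other countries".
* **Dose.** A report counts as "not exceeding routine" when its daily
  dose is less than *or equal to* the drug's routine daily dosage
  (fluconazole 400, voriconazole 400, posaconazole 300, itraconazole 200,
  isavuconazole 200 mg). Missing doses are counted separately and never
  enter the denominator.
* **Rounding.** All printed percentages are rounded half away from zero
  to 2 decimals, matching the convention of the published tables.

## The synthetic generator

Because the real database cannot ship with a package, every pipeline
stage is validated on generated data with exact ground truth. The
generator draws a background population plus study-drug reports and
renders them as the four "$"-delimited quarterly-style tables, together
with a manifest holding the true funnel counts, true contingency cells
and realized ROR per planted signal.

**Planting.** To plant a drug–event association with target ROR $r$, the
event's per-report probability for that drug is raised from the baseline
$q$ to $p = rq/(1 - q + rq)$ — i.e. the per-report event *odds* are
multiplied by $r$ — and the remaining event probabilities are rescaled to
keep the distribution normalized. Since the background keeps probability
$q$, the expected cross-product odds ratio equals $r$ while `b`, `c`, `d`
stay realistic.

**Duplicates** are exact copies of every one of a report's records,
sharing the report ID — the same case resubmitted across quarterly files,
which is what the 8-field key (which includes the report ID) is designed
to catch. The manifest counts inserted copies exactly, so dedup
conservation is tested with equality, not tolerance.

**Defaults.** The default configuration mirrors the screened triazole
cohort where the source states values: per-drug shares of study reports
(35/40/13/7/5%), cardiac event share 11.5%, mean age 55.24 (SD 15), sex
mix 45.7/41.4/12.9%, the published region mix, 55% serious with the
published serious-category mix, age missing 25%, dose missing 62%,
per-drug probabilities of exceeding the routine dose (6/12.6/60.2/44.2/50%),
and receive dates uniform over 2004-01-01 to 2022-09-30. Where no value
is stated, realistic choices were fixed once: a 30/25/30/5/10% role mix
over PS/SS/concomitant/interacting/unknown (echoing the ~28% PS share of
screened reports), a 5% duplicate rate, 1/rank frequency decay within the
event vocabulary, and a study-drug fraction of the database far above the
real ~0.5% so that drug–event cells are populated at desk scale.

**What it does not emulate.** Reporting biases (stimulated reporting, the
Weber effect), multi-drug/multi-event reports' correlation structure,
LLT-level coding, country-specific reporting cultures, and follow-up
versions that *differ* between submissions. Passing tests therefore show
that the pipeline's accounting and estimators behave as specified — not
that real FAERS extracts are free of the linkage and coding ambiguities
those features create.

## Validation problem sizes

The shipped suite validates: exact funnel/dedup conservation against the
manifest on a 7,500-report database; ROR/PRR equality with brute-force
odds/proportion ratios on ~4,300 small tables (relative error < 1e-12);
95% CI coverage within ±1.5 points of nominal over 2,000 multinomial
tables of 40,000 reports; planted log-ROR recovery with |bias| < 0.05
over 200 replicate universes of 9,000 reports (mean `a` ≥ 30); a null
flag rate below 5% over 20 unplanted replicates; byte-identical output
under a fixed seed; and replay of the dual criteria on the transcribed
published signal table, recovering the 13/11/26/5/1 per-drug signal
counts.

## Limitations

Disproportionality is association, not causation, and the ROR/PRR carry
all the usual caveats of spontaneous data. The package deliberately omits
Bayesian shrinkage methods (BCPNN/IC, MGPS/EBGM), SMQ event groupings,
LLT→PT coding, and probabilistic record linkage; the duplicate key is the
published 8-field rule, not FDA case-version reconciliation. The packaged
PT→SOC map is a fixture covering the cardiac SOC terms of the worked
example plus decoys — real analyses should supply a licensed MedDRA map.
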