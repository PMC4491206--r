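---
title: "Methods: screening, adjudication and validation of pediatric opioid toxicity in claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening, adjudication and validation of pediatric opioid toxicity in claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opitox)
```

## The problem and the design

Administrative claims record diagnoses, prescriptions and encounters, but
no direct indicator of "serious opioid toxicity". In children the problem
is harder than in adults: events are rarer, many toxicity symptoms (vomiting,
somnolence, respiratory findings) have broad differential diagnoses, and
adult-derived code sets do not transfer. The standard remedy is a two-step
phenotyping algorithm:

1. **Screen** — flag emergency-department visits, hospital admissions and
   deaths that carry suggestive ICD-9-CM codes *and* fall inside a
   prescription-anchored risk window, yielding *potential cases*;
2. **Adjudicate** — review each flagged record against structured clinical
   criteria, yielding *confirmed cases*;

with the screening strata validated by their **positive predictive value**
(confirmed / adjudicable). `opitox` implements both steps plus the
validation statistics and a calibrated synthetic-claims generator.

The design assumes claims with daily date granularity, ICD-9-CM coding, and
a precomputed opioid/other classification of fills (mapping NDC codes to
drug classes is upstream of this package).

## Risk windows and time strata

Each opioid fill opens its own follow-up window: toxicity is expected
during use, but "as-needed" dosing means actual use can outlast the
dispensed supply, so the window extends 14 days past the end of supply.
The package counts the fill day as supply day 1:

* `supply_end = fill_date + days_supply − 1`
* `window_end = supply_end + 14` (inclusive)
* early/late cutoff at `supply_end + 7`: events through the cutoff are
  "early", events on days 8–14 after supply end are "late".

The day-counting convention (fill day = day 1, all endpoints inclusive) is
a package choice; source descriptions of such windows rarely pin down the
convention, and off-by-one day choices move only events sitting exactly on
a boundary. Overlapping windows from refills are all retained; an event
covered by several windows is attributed to the **most recent qualifying
fill on or before it** — the pharmacologically dominant exposure — and one
potential case is emitted per child and event date, with a same-day death
superseding an encounter and category precedence (then encounter id)
breaking any remaining tie deterministically.

## Cohort eligibility

Eligibility is evaluated **per fill**, because each fill anchors its own
follow-up: the child must be 2–17 completed years old (inclusive bounds) on
the fill date, the fill inside the configured study window, and the 12
months (`lookback_days = 365`) strictly before the fill free of
serious-illness, transplant, institutional-residence and drug-abuse codes.
The lookback is anchored at the fill because "previous 12 months" is only
meaningful relative to the event that starts follow-up. A fill that fails
drops alone; a child with no surviving fill drops entirely. Exclusion
tallies per reason are attached to the cohort for funnel reporting.
Naloxone receipt is deliberately **not** an exclusion (it is commonly given
after procedures, not only for overdose). Continuous enrollment across the
lookback is available as a toggle (`require_continuous_enrollment`,
default off) since claims studies differ on whether gaps in coverage should
disqualify history assessment.

## Screening categories and the A/B/C rule

Four code families drive screening, all applied to ED/inpatient encounters
only (outpatient care is too nonspecific for serious toxicity):

| category | trigger |
|---|---|
| intentional overdose | self-harm poisoning external-cause codes |
| unintentional overdose | accidental/undetermined poisoning codes, opiate-poisoning diagnoses |
| adverse effect, therapeutic use | adverse-effect-in-therapeutic-use codes |
| symptoms only | serious CNS (altered consciousness) or respiratory (failure, arrest, apnea) diagnoses |

plus **any-cause death review**: every death dated inside a risk window is
flagged regardless of its cause codes, because death certificates
under-code drug involvement.

Because everyone in the cohort is a current or very recent opioid user,
the prior probability of opioid involvement in a drug event is high. The
three external-cause categories therefore carry three code groups each:
**A** (opioid or unspecified analgesic — always triggers), **C**
(unspecified medication — triggers on that prior), and **B** (a specific
non-opioid drug). The package's default rule is `A ∨ (C ∧ ¬B)`: an
unspecified-medication code is vetoed when the encounter names another
drug, but an explicitly coded opioid is never vetoed by a co-coded second
drug (mixed ingestions exist, and the opioid code is direct evidence).
The alternative scope — B vetoes A as well, `(A ∨ C) ∧ ¬B` — is available
as `b_veto = "AC"` for sensitivity analyses. When several categories fire
on one encounter, precedence is most-specific-intent-first: intentional >
unintentional > adverse effect > symptoms. Symptom codes are consulted only
when no external-cause category fired, so the strata are mutually
exclusive; the subtype (CNS / respiratory / both) is recorded for
symptom-only cases. The classifier is checked in the test suite against a
brute-force oracle enumerating all 1,024 combinations of ten trigger
groups, under both veto scopes.

Code lists live in a versioned YAML registry, not in source, because they
are study assets that reviewers revise. The bundled
`codesets.yaml` (version `reconstruction-1.0`) is assembled from standard
ICD-9-CM families — opiate poisoning 965.0x, accidental/undetermined
poisoning E850/E858/E980, self-inflicted E950, therapeutic adverse effects
E935/E947, narrow CNS and respiratory symptom codes — and is a documented,
usable default, **not** an authoritative published list. Deliberately out:
naloxone administration as a screening signal, metabolic-disorder symptoms,
dermatologic/GI symptoms without an adverse-effect code, and nonspecific
symptoms such as dizziness — signals with poor yield in this setting.
Prefix matching is the default (ICD-9 families are hierarchical); exact
matching is available per pattern (`=96500`); the canonical form is
dot-free upper case, since extracts vary in dot usage.

## The adjudication engine

Chart review is subjective; its *encoding* need not be. The engine maps a
structured abstraction — compatible signs/symptoms? attributed by the
treating physician to the opioid, or to another cause? escalation of care
for potential opioid toxicity? plausible temporal sequence? — to the three
mutually exclusive groups:

* **Group 1 (definite/probable):** compatible signs and symptoms attributed
  to the opioid with no other process implicated, *or* direct
  intervention/escalation of care for potential opioid toxicity;
* **Group 2 (possible):** compatible signs or symptoms, not clearly
  attributed to the opioid but not attributed to another cause, with a
  consistent temporal sequence;
* **Group 3 (excluded):** everything else.

The engine is a total function: the test suite enumerates all 64
combinations of the six decision flags against an independently written
scenario oracle. Severity on confirmed cases follows explicit dominance
death > high (hospitalization/escalation) > intermediate (primary reason
for an ED visit) > low (incidental), made explicit because a record can
set several flags at once. Exposure circumstances (self-harm, recreational,
unintentional overdose, therapeutic, withdrawal, unspecified) and opioid
source (own prescription, another person's, illegal, unspecified) are
closed vocabularies passed through unchanged — "unspecified" is retained,
never imputed. Urine/serum drug screens are not inputs: they are
inconsistently obtained and of limited diagnostic value for acute opioid
toxicity. Two-reviewer consensus never auto-resolves: disagreements are
flagged and take a supplied committee label, mirroring adjudication by the
full investigator panel.

## Validation statistics

Only PPV is computable under this design — screen-negatives are never
adjudicated, so sensitivity, specificity and NPV are out of scope. Each
stratum cell reports `x/n` with the Clopper–Pearson exact 95% interval
(beta-quantile closed form, cross-checked in tests against
`stats::binom.test`); a cell with `n = 0` is *undefined*, not 0%. Cases
whose records were unavailable or uninformative are excluded from all
denominators, and the funnel identity
`adjudicable = screened − no_information − not_found` is enforced, as are
the additivity identities (category totals and confirmed counts sum to the
overall cell; likewise the time strata). Reported tables round to one
decimal; tests compare unrounded values, since one-decimal rounding of
published tables is often loose (e.g. 25/31 = 80.645 can surface as either
80.6 or 80.7).

Reliability uses unweighted three-category Cohen's kappa,
`κ = (p_o − p_e)/(1 − p_e)` with `p_e` from the raters' marginals; a
binary collapse (confirmed vs excluded) can be computed by relabelling
before the call, but three categories is the default since the group
distinction is the instrument being tested. When both raters are constant
and identical, `p_e = 1` and kappa is returned as `NA` with a warning.

## What the synthetic generator emulates — and what it does not

`generate_claims()` emulates a pediatric Medicaid-like population: ages at
first fill drawn from a normal with mean 11.3 y, SD 5.0 y (the demographic
profile of the development population this package's defaults are
calibrated to), truncated to the eligible range; 57% female; 1 + Poisson(0.8)
opioid fills per child spaced 60 days apart inside a 2005–2010 study
window; days of supply in {3, 5, 7, 10, 14, 30} weighted toward short
courses. Per-category confirmation probabilities default to the validated
PPVs (15/30, 25/31, 33/58, 9/32, 3/15, 0 for deaths), record availability
to 168:4:23, early/late planting to 121:47, and reviewer agreement to
0.917. Planted encounters draw their codes from the *active* registry's
trigger groups, so custom registries stay testable; decoys — triggering
codes outside every window, benign codes inside windows, outpatient
encounters with triggering codes — are interleaved and must never screen
in, and a configurable fraction of children receive a lookback exclusion
code and must fall out of the cohort. One integer seed drives every draw;
identical parameters reproduce byte-identical artifacts.

The generator is a *verification instrument*, not a utilization model: it
does not model seasonality, refill adherence, coding error, comorbidity
correlation, dose, or drug-specific risk. Green tests on synthetic data
therefore demonstrate that the pipeline's logic is faithful to its stated
rules and that planted parameters are recovered — not that the shipped
code lists would achieve any particular PPV on real claims, which is
exactly why the registry is swappable configuration.

Default planted-case rates are sparse (a few per thousand fills),
claims-like. The calibration-recovery checks instead raise the per-fill
rates to 5–9% so that 20,000 simulated children realize roughly 1,500–3,000
adjudicable cases per stratum, making a 3-percentage-point recovery bound
a ≥3σ statement rather than a coin flip; those rates are chosen for
statistical resolution, not epidemiologic realism. At that scale the full
pipeline runs in well under a minute.

## Degenerate inputs and numerical conventions

* Empty bundles, empty case lists and `n = 0` cells flow through every
  stage without error, producing empty artifacts and undefined (`NA`)
  cells.
* `days_supply < 1`, reversed dates, unknown labels, unparseable codes and
  referential-integrity breaches fail fast with the offending row or id
  named.
* All I/O is deterministic: fixed column order, rows sorted by child then
  date, so re-running a stage is byte-identical and outputs are diffable.
* `lookback_days = 0` disables history exclusions; an empty Group B never
  vetoes; duplicate registry patterns deduplicate with a warning.

## Known limitations

Severity, intent and source classification exist only for confirmed cases,
so their distributions inherit any adjudication bias. The demonstration
study fixes intent/source quotas whose published analogues are internally
inconsistent by one case; the fixture uses the adjacent consistent
allocation (85 confirmed) and reproduces the published percentages to
rounding. Episode definition (one potential case per child-date) is one of
several defensible conventions; studies that count per-encounter episodes
will differ when a child has multiple qualifying same-day encounters. The
engine adjudicates abstractions, not charts: converting a medical record
into the abstraction remains expert work outside this package.
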