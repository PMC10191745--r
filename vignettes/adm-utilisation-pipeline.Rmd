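---
title: "Reconstructing pregnancy episodes and antidiabetic-medication utilisation from claims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pregnancy episodes and antidiabetic-medication utilisation from claims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Health-insurance claims record deliveries as billing codes — inpatient
DRG (diagnosis-related-group) codes and outpatient TARMED service codes in
the Swiss system — and record outpatient drug dispensations as ATC codes.
They do not record gestational age, the start of pregnancy, or a diagnosis
of diabetes. Studying antidiabetic-medication (ADM) use around pregnancy
from such data therefore requires three reconstruction steps, each of which
this package implements as a separately testable module:

1. **Delivery identification** — turn raw delivery codes, which arrive
   duplicated, split across two billing systems, and occasionally misdated,
   into one dated, term-classified delivery event per pregnancy.
2. **Pregnancy timing** — impute the last menstrual period (LMP) from the
   delivery date and term status, and lay out the analysis windows.
3. **Exposure classification** — map each pregnancy's ADM dispensations
   into those windows and classify the utilisation pattern.

Because real claims extracts are proprietary, the package ships a seeded
synthetic-claims generator with per-episode ground truth. The generator is
a first-class module: every pipeline rule is exercised against labels the
generator committed to before the pipeline ran.

## Delivery collapsing rules

Raw delivery codes for one person are reduced to delivery events by, in
order:

* **30-day clustering.** Codes within 30 days of a cluster's first code
  mark the same pregnancy. Clustering is anchor-based by default — the
  cluster window is measured from its first code, bounding a pregnancy's
  code spread at 30 days and making the result order-independent. The
  alternative transitive reading ("each code within 30 days of the
  previous") is available as `cluster_rule = "chain"` in `code_config()`
  because the verbal rule admits either reading.
* **DRG date priority.** A cluster's delivery date is its earliest code
  date, unless it contains an inpatient DRG code, in which case the
  earliest DRG date wins: DRG codes carry the admission-linked date and the
  term/preterm distinction.
* **The 31–300-day rule.** A DRG code recorded 31–300 days after an event
  that already has a DRG code cannot be a new delivery (deliveries must be
  ≥300 days apart) and is ignored — but recorded in the audit log, never
  silently dropped. If the earlier event was dated by a TARMED code alone,
  the late DRG code is instead taken to be the delivery's inpatient record:
  the event date is relocated to it and the term status re-derived. All
  later spacing checks use the relocated date.
* **Residual merging.** If discarding ignorable codes re-dates what remains
  of a cluster beyond the 300-day threshold, the remainder is a distinct
  delivery; otherwise a residual event closer than 300 days (TARMED-only
  stragglers, since only DRG codes trigger the ignore rule by default) is
  merged into the earlier event with a `merged_lt_separation` diagnostic.
  `ignore_rule_codes = "both"` extends the ignore rule to TARMED codes for
  sensitivity analyses.
* **Term status.** An event is preterm iff any member DRG code maps to
  preterm in the code configuration. `unspecified` codes and TARMED-only
  events default to full term — full term is the modal outcome and is the
  imputation's default branch.

A boundary note: the ignore rule covers offsets up to and including 300
days while the separation rule demands at least 300 days, so offset-300 is
claimed by both. The implementation gives the ignore rule precedence (a
DRG code exactly 300 days out is ignored; a new event requires >300 days),
which keeps all emitted events ≥300 days apart. The synthetic generator
never places codes on this boundary, so no tested behaviour depends on the
choice.

Pregnancies ending in miscarriage or termination are excluded: a
termination code within the 30-day collapsing window of a delivery event
removes that event (audit rule `termination_excluded`). Standalone
termination codes describe pregnancies that never produced a delivery and
simply yield no episode. Claims streams carry no episode linkage, so a
proximity rule is the only available implementation of "pregnancies ending
in termination"; the 30-day window mirrors the same-pregnancy rule.

## Pregnancy timing

The LMP is imputed as delivery − 270 days for full-term and delivery − 245
days for preterm deliveries, following the claims-validated imputation
algorithm in wide use. The LMP is day 0; all intervals are closed:

| window | days from LMP |
|---|---|
| prepregnancy | −252 … −1 |
| T1 | 0 … 89 |
| T2 | 90 … 179 |
| T3 | 180 … delivery (269 full term, 245 preterm) |

The windows tile `[LMP − 252, delivery]` exactly — no day uncounted, none
double-counted — which the suite verifies by day-by-day enumeration over
random episodes spanning leap years. An episode enters the cohort only if
enrollment spans cover every day from 252 days (9 months) before the LMP
to 252 days after delivery; abutting spans count as continuous. The
252-day reading of "9 months" after delivery mirrors the explicit 252-day
definition of the 9-month prepregnancy window and is configurable
(`post_delivery_days`) since the post-delivery requirement could also be
read as a calendar 9 months.

## Exposure and utilisation groups

Exposure is at least one outpatient dispensation of an ATC `A10` product in
a window; `A10A` maps to `insulin`, `A10B` to `blood_glucose_lowering`
(oral agents plus non-insulin injectables), remaining `A10` to
`other_adm`. Matching is case-insensitive longest-prefix, so the prefix
map absorbs codes recorded at any depth. A dispensation on the delivery
date counts toward T3 (closed-interval convention); later dispensations
are ignored.

Groups follow the standard utilisation taxonomy:

* **pregestational** — exposure in prepregnancy *and* in or after T2;
  subdivided into **continuers** (some ADM class present on both sides)
  and **switchers** (disjoint class sets — in practice an oral agent
  switched to insulin). Continuation is judged at the class level, which
  reproduces the documented mixed-regimen edge cases (e.g. insulin+oral
  before pregnancy, insulin only after T2 → continuer).
* **gdm** — first-ever exposure in or after T2, the claims proxy for
  pharmacologically treated gestational diabetes. The cutoff deliberately
  pools overt diabetes first treated in T2 with GDM; the two cannot be
  separated in claims.
* **discontinuer** — prepregnancy exposure with nothing in or after T2.
  An episode with prepregnancy *and* T1 exposure but nothing later is
  still a discontinuer by definition; it is distinguishable downstream via
  the per-window class columns.
* **t1_only** — exposure beginning in T1, which the three definitions
  above do not cover: forcing first-exposure-in-T1 episodes into the GDM
  group would contradict "first time in or after T2". Subtype
  `t1_first` marks T1 starters who continue in or after T2.
* **unexposed** — everything else.

The six labels partition every cohort; the suite checks the partition and
the switcher-disjointness invariant on random profiles.

## Prevalence estimation

Rates are reported per 10,000 deliveries with 95% binomial confidence
intervals. The interval method is Clopper–Pearson exact (via the beta
quantile function), chosen because the reported zero-count interval
behaviour (upper bound `1 − 0.025^(1/n)`) identifies an exact rather than
asymptotic method; Wilson score intervals are available through
`ci_method = "wilson"` for users who prefer shorter intervals at these low
prevalences. Reported values are rounded half-up to one decimal at
presentation only; all internal arithmetic is exact. Ratios of
already-rounded per-10k rates can disagree with count-based ratios in the
last decimal, so the pipeline reports from raw counts and exposes
`proportion_pct()` as the explicit presentation-layer helper for
rounded-rate arithmetic.

## The synthetic generator

`generate_cohort()` emulates the structural features of the real claims
streams that the pipeline's rules exist to handle: women with one or more
deliveries, a DRG/TARMED code mix, duplicate codes within 30 days, stray
DRG codes 31–300 days after a delivery, TARMED-dated deliveries later
corrected by their DRG code, enrollment gaps, refill sequences, and
non-ADM background dispensations. Its defaults are the study conditions of
the cohort the pipeline targets: pregestational diabetes 25.9/10,000
(85.3% continuers; class mix 88.2/6.5/5.2 insulin-only/both/oral-only),
GDM 257.7/10,000 (98.8% insulin-only), discontinuers 10.7/10,000 (75.7%
oral, 32.1% of those with fertility comedication), caesarean rate 31.9%,
mean maternal age 31.7, substance mixes led by insulin aspart (42.3%) and
metformin (66.1%). Values no published source pins down were fixed once at
field-realistic levels: parity distribution 78/20/2% for 1/2/3 deliveries
in-window, preterm rate 7%, a 45-day refill cadence, and a 5/10,000
t1-only prevalence.

Two generator choices make ground truth well-defined by construction:

* dispensation dates are drawn with a one-day margin inside every window
  boundary, so the intended window assignment cannot hinge on an
  interval-endpoint convention;
* successive deliveries of one woman are at least 530 days apart, so one
  pregnancy's observation window can never overlap the next pregnancy's
  prepregnancy window (252 + 270 = 522 days), and a dispensation belongs
  to exactly one episode.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: the real Swiss code lists (the shipped
DRG/TARMED values are labelled synthetic placeholders; real analyses must
supply their own `code_config()`), calendar trends and seasonality,
maternal-age structure of risk, inpatient medication use, prescriptions
recorded under national product numbers rather than ATC, miscarriage and
termination dynamics, and closely spaced pregnancies whose observation
windows genuinely overlap. Recovery of 100% of ground-truth labels shows
the pipeline implements its stated rules exactly; it does not validate the
LMP imputation itself, which rests on external validation work.

## Problem sizes and numerical choices

The test suite runs the oracle-equivalence comparison on 220 random code
streams against an independently written rule-by-rule reference,
label-recovery on a 100-woman noise-free cohort, pathology audits on a
300-woman cohort with all noise channels on, and prevalence recovery on a
17,000-woman (~20,000-delivery) cohort, where programmed group prevalences
must be recovered within three binomial standard errors. The acceptance
script regenerates the 20,000-delivery cohort from a caller-supplied seed
and recomputes all headline quantities from scratch. Sub-seeds for the
generator are derived deterministically from the single user seed and stay
below 2^31.

Known limitations: day-resolution dates only (claims carry no times);
per-10k rounding can make within-group percentages differ by ±0.1 from
count-based values; the fertility-comedication flag depends entirely on
the configured ATC prefix list; and clomiphene-type products recorded
outside the ATC system are invisible to the dispensation model.
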