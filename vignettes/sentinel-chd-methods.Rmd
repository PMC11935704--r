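---
title: "Methods: long-term outcome metrics for sentinel congenital heart diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-term outcome metrics for sentinel congenital heart diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

National congenital cardiac audits are procedure-based: each row is one
cardiac surgery or interventional catheterization, carrying diagnosis and
procedure codes. Reporting long-term, diagnosis-based outcomes from such data
requires several nontrivial steps before any survival curve can be drawn:

1. linking procedure rows into patient histories via pseudonymous ids;
2. assigning each patient one *sentinel diagnosis* (and subgroup) from the
   diagnosis codes pooled across all their records;
3. classifying each procedure's role in the *expected treatment pathway* for
   that diagnosis — prepathway (e.g. balloon atrial septostomy), staged
   single-ventricle palliation (stage 1, Glenn, Fontan), or reparative
   surgery — each slot fillable once per patient;
4. adjudicating everything beyond the expected pathway as *reintervention*;
5. flagging implausible sequences (suspected missing or miscoded data);
6. ascertaining life status from audit and mortality-register sources with a
   fixed precedence; and
7. estimating survival (Kaplan–Meier) and cumulative incidence of
   reintervention (Aalen–Johansen, with death and transplant without prior
   reintervention as competing events) at ages 1, 5 and 10 years.

`sentinelchd` implements this pipeline for nine sentinel diagnoses (HLHS,
functionally univentricular heart, TGA, pulmonary atresia, AVSD, tetralogy
of Fallot, aortic stenosis, coarctation, VSD), together with a calibrated
synthetic registry generator so the whole pipeline is testable without
access-controlled registry data.

## Phenotyping

Diagnosis concepts are pooled across **all** of a patient's records, not
just the first: later procedures often carry fuller diagnostic coding.
Assignment is therefore a pure function of the pooled concept multiset,
invariant to record order and duplication. When markers of several sentinel
diagnoses co-occur, the most clinically complex wins, with precedence

> HLHS > FUH > TGA > PA > AVSD > TOF > AS > coarctation > VSD.

This order, and the per-diagnosis subgroup rules, live in a versioned
ruleset file (`inst/extdata/ruleset.yaml`) so refined clinical rule tables
can replace the bundled ones. Two deliberate consequences of the precedence
design: a pool containing both coarctation and VSD markers is *coarctation
plus VSD* (a coarctation subgroup), and a pool with both tetralogy and AVSD
markers is *tetralogy-AVSD* (an AVSD subgroup). Persistent ductus
arteriosus and other recognized non-sentinel codes yield diagnosis `none`
(excluded as not sentinel, distinct from records with no cardiac codes at
all).

Each diagnosis has a residual subgroup that applies when no modifier marker
is present (e.g. standard tetralogy, isolated VSD, TGA with intact septum).
The functionally univentricular group has no natural residual in its
two-subgroup split; the package treats tricuspid atresia as the residual
(double-inlet ventricle requires its marker), which is the more prevalent
subgroup in national data.

Raw clinical codes are abstracted behind a *concept dictionary*
(`inst/extdata/concepts.yaml`): raw code → concept, concept → pathway role
per diagnosis, plus diagnosis/subgroup/comorbidity/prematurity markers. The
bundled dictionary is synthetic (real code lists are licensed); real
mappings plug in through the same file format.

## Pathway classification and reintervention adjudication

Scanning records in age order (ties keep input file order — registry
extracts list same-admission procedures in entry order), the first record
bearing each role fills that slot; each defined pathway procedure can occur
only once per patient. The adjudication conventions, where the underlying
reporting rules leave room, are:

* **Repeat pathway procedures** (a reoperation) are reinterventions.
* **Stage monotonicity**: slot ages must satisfy stage 1 ≤ stage 2 ≤
  stage 3. A stage-k record arriving after a later stage's slot is already
  filled (only possible in miscoded data) is adjudicated as reintervention
  rather than violating monotonicity.
* **Prepathway window**: 'other'-role records after the first pathway
  (stage/repair) procedure are reinterventions; before it, only therapeutic
  ones count (modality other than electrophysiology). Prepathway records are
  never reinterventions.
* **Transplant** is identified by a dedicated concept; it sets the
  transplant age and acts only as a competing event, never as a
  reintervention.
* **Same-day ties**: if two role-bearing records share an age, file order
  decides which fills the slot; the other becomes a reintervention.

Pathway type is single-ventricle iff a stage-2/3 slot is filled with no
repair, biventricular iff a repair is filled with no stage-2/3, and
indeterminate otherwise (both or neither); indeterminate with both filled is
picked up by the quality rules.

Staged-palliation roles are defined for every diagnosis — including the
exclusively biventricular ones — precisely so that a miscoded Glenn in a
VSD history can fill a slot and trigger a flag rather than silently counting
as a reintervention.

## Quality flags

The concrete rule list used in national reporting is clinical-expertise
driven and not published; the package ships a documented, configurable
reconstruction (`q1`–`q5`, see `?flag_patients`): missing stage 1 under a
stage 2, missing stage 2 under a stage 3, staged palliation in an
exclusively biventricular diagnosis, repair plus staged palliation
(indeterminate), and an implausibly late first procedure (bounded per
diagnosis; the default bounds only constrain HLHS, where essentially all
first procedures occur in the first weeks of life). Flagged patients are
excluded from reintervention metrics but retained for survival metrics (the
reporting convention for the reintervention tables states the exclusion;
the survival tables do not) — the scope is switchable via
`exclude_flagged_reint`.

## Life status and estimation

Life-status precedence: audit-recorded death age, then mortality-register
death age, then the register's alive-confirmation age (censoring); patients
with no register information are lost to follow-up and censored at their
most recent discharge age.

The time origin is **birth** (age scale), not the procedure date, so the
metrics are survival *to ages* 1, 5 and 10 years (365.25·k days; all
internal ages are integer days).

* **Kaplan–Meier**: product-limit over distinct death ages, Greenwood
  variance accumulated on the log scale, 95% CIs via the log(−log)
  transform (bounded in [0, 1]). Deaths are processed before censorings at
  tied ages (a patient censored at *t* remains at risk for a death at *t*).
  With no deaths the estimate is identically 1 and the interval degenerates
  to an absent lower limit and upper limit 1.
* **Aalen–Johansen**: F_k(t) = Σ_{t_i ≤ t} Ŝ(t_i−) d_ki/n_i with Ŝ the
  all-cause event-free KM; first-event-per-patient semantics with follow-up
  ending at the first of reintervention, death, transplant or censoring.
  Variance by the standard delta-method (Marubini–Valsecchi) estimator and
  CIs via the complementary log-log transform. A tie between reintervention
  and death at the same age resolves as reintervention (the event of
  interest ends follow-up). Additivity Σ_k F_k + Ŝ = 1 holds exactly at
  every step by construction.
* **Type-specific analyses**: surgical = {bypass, non-bypass, hybrid};
  interventional cardiology = {catheter, electrophysiology}. The first
  reintervention *of that type* is the event; death/transplant compete;
  other-type reinterventions do not end follow-up. The grouping is
  configuration, not code.

Both estimators are authored in the package and cross-checked in the test
suite against independent implementations (`survival::survfit` with
log-log intervals; `cmprsk::cuminc`) and against brute-force product-limit
and Aalen–Johansen oracles on hand-sized cohorts.

## The synthetic registry generator

The generator emulates a 22-year national cohort of the nine sentinel
diagnoses: per-diagnosis cohort sizes, subgroup mixes, log-normal
age/weight-at-first-procedure distributions (median/IQR-matched),
prematurity and comorbidity rates, staged and biventricular pathway
templates, death and reintervention hazards, ~2% loss to follow-up, and a
1% corruption rate producing implausible sequences. Its defaults are the
study conditions; they are set once in `default_block_table()` and not
tuned per test.

**Hazards.** Death, transplant and reintervention times are drawn from
independent piecewise-constant hazards on the age segments [0,1), [1,5),
[5,10), [10,∞) years — chosen because closed-form survival and
competing-risks cumulative incidence at the three report ages are then
available. The death hazard is solved in closed form from the survival
targets; the reintervention hazard is solved segment-by-segment by
`uniroot` against the closed-form competing-risks CIF (competing hazard =
death + transplant). `implied_survival()` and `implied_reint_cif()` expose
the exact implied values, which are what the recovery tests check coverage
against.

**Pathway templates.** Single-ventricle patients attain stage 1 with
probability p₁, stage 2 given stage 1 with p₂, stage 3 given stage 2 with
p₃; inter-stage gaps are log-normal with default medians ≈ 4 months
(stage 1→2) and ≈ 3 years (stage 2→3), log-sd 0.45 — defaults chosen as
clinically typical and fully overridable. Mixed diagnoses (TGA, PA, AVSD)
follow the single-ventricle route with the spec's `sv_fraction`, otherwise
a biventricular template (optional palliation then repair). Attainment
probabilities are conditional on being alive at the scheduled time; death,
transplant and the administrative horizon truncate subsequent procedures.

**Consistency devices** (each keeps an estimator unbiased):

* For the few patients whose sampled death precedes their sampled first
  procedure age, the first procedure is clipped to the day before death
  (the death marginal is untouched, so implied survival stays exact).
* A patient attaining no pathway procedure and no reintervention receives a
  prepathway record, so every patient has ≥ 1 record without inflating
  reintervention incidence (prepathway is never adjudicated as
  reintervention).
* Loss to follow-up is modelled as a loss *time* (uniform over the
  patient's potential follow-up, emulating emigration or unlinkable
  records): procedures, transplants and deaths after the loss are
  unobserved, and the patient has no mortality-register columns (a death
  before the loss appears in the procedure audit only). Observation stops
  wholesale at an age independent of the event processes — an earlier
  design that kept post-loss procedure records observable made late
  reinterventions of lost patients always-observed events and visibly
  inflated the estimated incidence.

**Corruption.** The default policy picks, per selected patient, an
operation the quality rules can detect: delete the stage-1 record under a
stage 2 (→ q1), insert a staged-palliation record into a biventricular
history (→ q3/q4), or insert a Fontan-type record with no Glenn (→ q2).
(An undetectable "duplicate the repair as an unlabeled same-day row"
operation is also implemented, selectable via `ops`, but deliberately not
in the default policy: the design goal is that the flagged fraction tracks
the injected fraction, which a silent duplicate would break.) On clean
cohorts the rules fire nowhere — the suite asserts zero false positives —
and every injected corruption is flagged.

**Randomness.** Each diagnosis block draws from a sub-stream derived from
the master seed and the block name, so editing one block's parameters does
not reshuffle the others; the corruption pass has its own sub-stream.

**What the generator does not emulate:** center effects, era/seasonal
trends, correlation between age and weight at first procedure (sampled
independently; the real joint distribution is unpublished), post-transplant
hazard changes, and within-admission coding detail. Passing recovery tests
therefore demonstrate that the pipeline's logic and estimators are correct
under the stated statistical structure — not that real registry extracts
are free of the coding pathologies the quality rules exist for.

## Problem sizes and numerical choices

The recovery test suite runs each of the nine diagnosis blocks at
n = 2000 patients for 50 seeded replicates and requires the spec-implied
survival (1/5/10 y) and 10-y reintervention incidence to fall inside the
estimated 95% CI in at least 90% of replicates; classification-recovery
checks run one full-size cohort (29 319 patients). These sizes were chosen
so the binomial and coverage bands are tight enough to be meaningful while
the suite stays comfortably interactive. Other numerical conventions:
`uniroot` tolerance 1e-12 for hazard calibration; CIF additivity asserted
to 1e-9; Greenwood terms at exhausted risk sets (n = d) contribute zero;
percentages in summary tables are rounded to one decimal.

## Known limitations

* The bundled concept dictionary and subgroup marker sets are synthetic
  approximations with the right structure, not the licensed national code
  lists; the distinction between complex TGA variants, in particular, is a
  documented approximation.
* Only the nine sentinel diagnoses are subgrouped; the other candidate
  diagnoses are recognized solely as "not sentinel".
* The analysis is deliberately descriptive: no covariate adjustment, no
  center-level comparison, no era effects.
* Follow-up for type-specific reintervention incidence treats other-type
  reinterventions as irrelevant rather than competing; alternative
  conventions exist and would need a one-line change in
  `build_event_histories()`.
* Censoring lost-to-follow-up patients at their most recent discharge age
  is itself mildly informative for the reintervention analysis: a lost
  patient with no further procedure exits the risk set at their last
  (early) discharge, whereas a lost patient whose loss came after a
  reintervention contributes that event — so procedure-driven censoring
  slightly inflates the estimated incidence. In simulation this is
  measurable (about +0.3 absolute percentage points on a 21% incidence at
  2% loss, vanishing as the loss rate goes to zero) and is a property of
  the discharge-based censoring rule, not of the estimator; the recovery
  tests pass with it present.
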