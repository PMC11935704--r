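# sentinelchd

Long-term outcome metrics for sentinel congenital heart diseases (CHDs)
from procedure-level registry records.

## The problem

National congenital cardiac audits record one row per procedure, not per
patient, and routinely report only short-term postoperative outcomes.
Patients, clinicians and commissioners want the longer view: for a child
born with, say, hypoplastic left heart syndrome, what are the chances of
being alive at ages 1, 5 and 10 years, and of needing a further cardiac
intervention beyond the expected staged treatment course?

Answering that from registry extracts requires a pipeline, and this package
implements it end to end for nine sentinel CHD diagnoses — hypoplastic left
heart syndrome (HLHS), functionally univentricular heart (FUH),
transposition of the great arteries (TGA), pulmonary atresia (PA),
atrioventricular septal defect (AVSD), tetralogy of Fallot (TOF), aortic
stenosis (AS), coarctation of the aorta, and ventricular septal defect
(VSD):

* **registry I/O** — read procedure and life-status tables, translate raw
  clinical codes through a configurable concept dictionary, link rows into
  patient histories;
* **phenotyping** — assign one sentinel diagnosis and subgroup per patient
  from the pooled diagnosis concepts, with a clinical-complexity precedence
  order, plus prematurity/comorbidity flags and cohort exclusion rules;
* **pathway classification** — label each procedure's role in the expected
  treatment pathway (prepathway, stage 1 palliation, Glenn, Fontan,
  reparative surgery; each slot fillable once) and adjudicate everything
  beyond it as reintervention;
* **quality flags** — detect implausible sequences (e.g. a Glenn with no
  stage 1) and exclude those patients from reintervention metrics;
* **outcomes** — ascertain life status with audit-then-register precedence
  and estimate the metrics;
* **synthetic registry** — a seeded, calibrated generator so the entire
  pipeline is testable without access-controlled data.

## The statistics

Survival on the age scale (origin birth) uses the Kaplan–Meier
product-limit estimator

  S(t) = ∏_{t_i ≤ t} (1 − d_i / n_i),

with Greenwood variance and 95% CIs on the log(−log S) scale. Cumulative
incidence of reintervention treats death and heart transplant without prior
reintervention as competing events, via the Aalen–Johansen estimator

  F_k(t) = ∑_{t_i ≤ t} Ŝ(t_i−) · d_ki / n_i,

where Ŝ is the all-cause event-free Kaplan–Meier; variances use the
standard delta-method estimator and CIs the complementary log-log
transform. Both estimators are implemented in the package and cross-checked
in the test suite against `survival::survfit`, `cmprsk::cuminc`, and
brute-force oracles.

The synthetic generator draws death, transplant and reintervention times
from independent piecewise-constant hazards on the age segments [0,1),
[1,5), [5,10), [10,∞) years, calibrated in closed form so that the implied
survival and reintervention incidence at the report ages equal stated
targets (see `implied_survival()`, `implied_reint_cif()` and the methods
vignette).

## Worked example

Simulate two diagnosis blocks at their default cohort sizes and run the
full pipeline:

```r
library(sentinelchd)

spec <- default_cohort_spec(c(HLHS = 1296, FUH = 0, TGA = 0, PA = 0,
                              AVSD = 0, TOF = 0, AS = 0, COARCT = 0,
                              VSD = 6575))
bundle <- run_pipeline(run_config(simulation_spec = spec, seed = 2024))

m <- bundle$metrics[bundle$metrics$level == "diagnosis", ]
```

which prints (seed 2024):

```
HLHS  n=1296  10y survival 57.3% (54.4%-60.0%)  10y reintervention 54.8% (51.8%-57.6%)
VSD   n=6575  10y survival 96.9% (96.4%-97.3%)  10y reintervention 6.5% (5.8%-7.1%)
flagged: 88 of 7871 (1.1%)
```

Reading the numbers: of the simulated HLHS cohort, an estimated 57.3% are
alive at age 10 (the widest-severity end of the sentinel spectrum), and
54.8% have had at least one cardiac reintervention beyond the staged
pathway by that age, with death/transplant treated as competing events; for
VSD — the mildest and most prevalent diagnosis — the same metrics are 96.9%
and 6.5%. About 1% of records are flagged as implausible sequences (the
generator's injected corruption rate) and are excluded from the
reintervention estimates. The bundle also carries the inclusion flow chart,
per-slot pathway completion (e.g. 97.3% of unflagged HLHS patients reached
stage 1, 61.2% a Glenn, 26.4% a Fontan in this draw), scoping metrics, and
per-patient traces.

A thin command-line wrapper is available at `inst/cli/sentinelchd.R`
(`simulate` and `analyze` subcommands).

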