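# stoppcds

Potentially inappropriate prescriptions (PIPs) — prescriptions that published
criteria flag as likely to do an older patient more harm than good — are a
leading, largely preventable source of drug-related morbidity in primary
care. The STOPP criteria (Screening Tool of Older People's Prescriptions)
express most of these as simple conditions over coded data: *a patient aged
65 or over, on drug class X, with condition Y on the problem list*. That
makes them natural candidates for EMR decision support — and makes their
firing rate exquisitely sensitive to whether drug and problem data are
actually coded.

`stoppcds` is a complete, tested implementation of the computational
apparatus such a study needs, for methodologists and EMR researchers who
want to run, audit, or simulate it:

* **a rule engine** over four coded EMR tables (patients, encounters,
  medications, problems), with a deliberately restricted predicate language
  (`AGE_GE`, `ON_MED`, `HAS_PROBLEM`, `GENDER_IS`, boolean combinators — no
  dose or duration logic, by construction) and a shipped library of 40
  STOPP-style rules, each split into a *scope* (opportunity) and a *fire*
  (inappropriateness) predicate with `fire ⇒ scope` enforced at load time;
* **PIP measurement**: per clinic and 16-week window, the rate
  `100 · Σ fired / Σ eligible` over (patient, rule) pairs, where a pair is
  eligible iff the scope predicate holds — the "possible PIPs" denominator;
* **twelve data-quality probes** (dq1–dq12): completeness of demographics,
  medication coding, problem-list usage, and drug–diagnosis concordance
  (tiotropium↔COPD, levothyroxine↔hypothyroidism, anti-gout↔gout), all
  restricted to patients *calculated* as active (an encounter in the past
  24 months);
* **an aggregate-only query contract**: clinics compute locally and emit
  only `{measure, window, numerator, denominator}` records — the answer
  type has no slot a patient identifier could occupy;
* **trial statistics**: difference-in-differences summaries; a
  clinic-clustered GEE (binomial logit, exchangeable working correlation,
  sandwich variance, Wald test referred to *t* with `clinics − 4` df) for
  the arm × period interaction

  `logit P(fire) = β₀ + β₁·arm + β₂·period + β₃·(arm × period)`;

  and two-proportion sample-size / power calculations with a cluster
  design effect `1 + (m − 1)ρ`;
* **a seeded synthetic EMR generator** whose knobs (coding fraction,
  ghost-active fraction, problem-list usage, planted PIP prevalence,
  treatment effect, …) each correspond to a probe or measurement, so every
  knob is recoverable — and whose corruption step (uncoded prescriptions,
  missing demographics) is applied *after* planting, so the attenuation of
  detectable PIPs by poor data quality is itself measurable.

## Worked example

Generate a paper-like null study (8 clinics, 4 per arm, stratified small /
large; control arm: 5% elderly, 79% coded medications, 2.6% planted PIP
prevalence; intervention arm: 19% elderly, 82.3% coded, 4.0%), measure it
through the aggregate-only pipeline, and analyze:

```r
library(stoppcds)

cfg   <- paperlike_config(patients_per_clinic = 5000, seed = 42)
study <- generate_study(cfg)
lib   <- default_rule_library()

answers <- lapply(study$clinics, clinic_respond, lib = lib,
                  windows = study$windows, ref_date = study$ref_date)
hub <- hub_collect(answers)
print(hub)
#> <hub_collection> 8 clinics, rule library stopp40-1.0
#>   control      baseline       2 / 61      (3.28%)
#>   intervention baseline      36 / 768     (4.69%)
#>   control      treatment      2 / 47      (4.26%)
#>   intervention treatment     38 / 838     (4.53%)

summarize_trial(hub)
#> PIP rates (%) by arm and period
#>   intervention baseline 4.7 | treatment 4.5 | change -0.2
#>   control      baseline 3.3 | treatment 4.3 | change 1.0
#>   difference-in-differences: -1.2 percentage points

gee_test(hub_pip_counts(hub))
#> <gee_fit> arm:period log-odds -0.2571 (robust SE 0.3071), t = -0.837 on 4 df, p = 0.45
#>   8 clinics, exchangeable working correlation alpha = 0.173
```

The study was generated under the null (`treatment_effect = 1`), and the
GEE finds nothing: the interaction log-odds is small against its robust
standard error. The per-arm rates recover their planted prevalences
(intervention ≈ 4%, control ≈ 2.6% up to the small control denominators —
only 5% of its patients are elderly and 84.6% carry no current
medications, exactly the sparsity that makes measured PIP rates so much
lower than the 20% literature rates a power calculation would assume).

The planning side:

```r
sample_size(p_control = 0.20, relative_reduction = 0.20,
            encounters_per_clinic = 120)
#> n per arm: 1445; clinics per arm at 120 encounters: 13
```

Per-clinic data-quality reporting:

```r
run_all_probes(study$clinics[["CL01"]], study$ref_date)   # dq1..dq12
```

A thin command-line front end (`inst/cli/stopp-pip`) exposes the same
pipeline as `simulate`, `measure`, `probes`, `respond`, `hub-collect` and
`analyze` subcommands.

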