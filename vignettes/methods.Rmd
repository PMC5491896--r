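---
title: "Measuring potentially inappropriate prescribing from coded EMR data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring potentially inappropriate prescribing from coded EMR data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoppcds)
```

`stoppcds` implements the measurement and analysis machinery of a
cluster-randomized evaluation of STOPP-style prescribing rules delivered
as EMR decision support. This vignette is the package's own account of
the science inside it: what is modelled, what is assumed, which knobs
matter, and where the honest limits are.

## The rule model

A prescribing criterion is two predicates over one patient's coded
records in a time window:

* **scope** — the *opportunity* condition: the patient could trigger this
  criterion (always `ALL_OF(AGE_GE(65), ON_MED(anchor-class))` in the
  shipped library);
* **fire** — the full condition: the prescription is potentially
  inappropriate (`ALL_OF(scope, extra)`, where the extra conjunct is a
  problem-list condition, a co-prescribed drug class, or the *absence* of
  a documented indication).

The split matters because it defines the primary outcome. A "possible
PIP" is a (patient, rule) pair whose scope holds; the PIP rate is
`100 · Σ fired / Σ eligible`. Anchoring the denominator on the scope
predicate — age *plus* the anchor drug condition, not merely age 65+ —
yields a few eligible rules per at-risk patient (about 5 at the default
configuration), which is the regime in which per-rule and overall rates
are both interpretable. This denominator definition is the single most
consequential design choice in the package and is deliberately prominent
here.

Assumptions baked into evaluation:

* **Missing data are false.** An atom over absent or uncoded data
  evaluates to `FALSE`, never to an error. An uncoded (free-text)
  prescription is invisible to `ON_MED`; a patient without a birth date
  satisfies no age predicate; `NOT(HAS_PROBLEM(x))` is `TRUE` on an empty
  problem list. This mirrors how coded-data decision support actually
  behaves, and it is the mechanism by which poor documentation silently
  suppresses alerts — the package keeps it explicit so it can be tested
  and quantified rather than discovered in production.
* **Medication currency is interval overlap**: active in the window iff
  `start ≤ window_end` and (`end` missing or `end ≥ window_start`), with
  a missing end meaning open-ended. No duration accumulation across
  refills exists, by construction.
* **Problems are cumulative.** A problem list is a status register, not
  an event log; an entry documented before the window still counts. This
  is how drug–disease criteria are read clinically.
* **Counting is patient-level.** A (patient, rule) pair contributes at
  most once per window regardless of prescription or encounter
  multiplicity; event-level denominators cannot be audited from
  aggregate answers.
* **The DSL is deliberately incomplete.** There is no dose-threshold and
  no duration predicate, so criteria needing them are unrepresentable —
  the same boundary a simple EMR rules engine imposes. The shipped
  40-rule library is an implementer's reconstruction *in kind* of the
  STOPP v1/v2 subset expressible under that restriction; it is engine
  fixture content with conventional ATC/ICD-9 mappings, not clinical
  guidance, and the code sets are configuration a deployment must
  review.

Date arithmetic is pinned: ISO-8601 strings, closed intervals, whole
days, and "past *N* months" = `floor(N · 365.25 / 12)` days, so a
24-month lookback is exactly 730 days. Without a fixed convention, probe
values would not be reproducible across implementations.

## Data-quality probes

The twelve probes (dq1–dq12) measure completeness and concordance of the
three EMR areas the rules consume: demographics (no gender, invalid or
absent birth date — *invalid* meaning present but unparsable, in the
future, or implying age over 120), medications (fraction of current
prescriptions coded; fraction of patients with none), and the problem
list (recent-problem usage, diabetes prevalence, and three
drug–diagnosis concordance checks). All are restricted to
*calculated-active* patients — at least one encounter in the 24 months
before an explicit reference date, never "today" — because the EMR's own
active flag routinely includes patients who left years ago (dq1 measures
exactly how many). Probes measure documentation, not truth: they cannot
distinguish an undiagnosed patient from an undocumented one. A
thirteenth probe id is reserved but intentionally not implemented.

## The aggregate-only contract

Measurement runs inside each clinic; only
`{measure, window, numerator, denominator}` records cross the boundary.
Privacy is enforced structurally — the answer type has no field that
could carry a patient identifier or date — and verified behaviorally by a
leak-scan test that greps serialized answers for every patient id in the
source data. Arm totals are exact integer sums of clinic answers
(conservation), so the hub's rates are reproducible from the per-clinic
files alone. Small-cell suppression (masking numerators 1–4) is
available but off by default; it is a deployment policy, not part of the
measurement definition.

## The synthetic population

`generate_study()` draws a multi-clinic population in which **every knob
is recoverable by a matching measurement**: ghost-active fraction ↔ dq1,
coding fraction ↔ dq5, medication-free fraction ↔ dq6, problem-list
usage ↔ dq8, diabetes ↔ dq9, concordance ↔ dq10–12, planted PIP
prevalence ↔ `measure_pips`. PIPs are planted abstractly per
(patient, rule) via scope/fire probabilities and then materialized as
concrete coded records; realistic longitudinal prescribing is not
simulated because the measurement consumes only scope/fire events.

Mechanics worth knowing when interpreting results:

* **Corruption comes after planting.** Anchor prescriptions are uncoded
  with probability `1 − coded_med_frac`, which destroys the pair's
  *detectability* (it leaves both numerator and denominator) without
  changing its truth. The generator records planted truth per clinic,
  rule and window, so observable ≤ true is an invariant and the
  attenuation is itself measurable. Fire-completing co-prescriptions on
  drug–drug rules are written as coded; otherwise the conditional fire
  rate would be `pip_prevalence × coded_med_frac` rather than the knob,
  and the generator's contract is that knobs come back.
* **Identifiability shaped the rule library.** Drug-drug extras
  (opioids, SSRI, warfarin, verapamil) anchor no rule: if an extra class
  also anchored another rule, planting both anchors would fire the pair
  at the anchor prevalence regardless of the fire knob. Background
  medication and diagnosis pools are disjoint from every rule and probe
  code set for the same reason (asserted by test).
* **Treatment effects act through dischargeable rules.** A documented
  problem cannot be un-documented mid-study, so only drug–drug criteria
  (share 0.15 of the library) can stop firing between windows. The
  multiplicative `treatment_effect` is rebalanced onto that subset so
  the *overall* intervention treatment-window rate scales as requested;
  effects below `1 − 0.15 = 0.85` are rejected as unrealizable rather
  than silently diluted. Calibration studies of the test statistic do
  not need materialized records at all and run on
  `simulate_trial_counts()`, the counts-level core the GEE consumes.
* **What is not emulated:** refill chains and dosing, free-text notes,
  seasonal encounter patterns, correlation between comorbidity and
  medication burden beyond age, and clinic-level heterogeneity in the
  planted rates (clinics differ only through sampling noise and the
  arm-level knobs). Passing recovery tests therefore shows the pipeline
  is *internally* consistent — that measurement inverts generation — not
  that real EMR data will be as well behaved; on real extracts the
  probes exist precisely because it will not be.

The paper-like configuration (`paperlike_config()`) sets the knobs to
the observed per-arm field values of the trial the package models
(coding 82.3%/79.0%, problem-list usage 12.3%/3.5%, elderly share
19%/5%, ghost-active complements of 35.7%/28.6%, PIP prevalence
4.0%/2.6%, null effect) with 8 clinics stratified small/large as in the
study, and a scaled-down default of 2,000 flagged-active patients per
clinic so a full study generates in about a second. At that scale the
control arm is *sparse* — a handful of eligible patients per clinic per
window, occasionally zero — which is faithful to the phenomenon (5%
elderly, 84.6% without medications) but means small-sample runs should
use 5,000 patients per clinic, the size the package's own recovery tests
use.

## Trial statistics

**Rates and differences.** Arm×window rates are exact integer ratios;
per-arm change and the difference-in-differences are computed at full
precision, with display values rounded (1 d.p. by default, configurable
to 2 where a 4.11-style value would round ambiguously) and displayed
changes formed from displayed rates so printed tables are
self-consistent.

**The GEE.** The intervention test is a binomial-logit marginal model
with covariates arm, period and arm×period, an exchangeable working
correlation within clinic, and the sandwich covariance taken over
clinics. It is fit on clinic×window binomial aggregates: all members of
a cell share one covariate row, so the estimating equations collapse
onto the cell proportions and the aggregate fit is score-equivalent to
the patient-level one under this design. The working correlation is
estimated by the usual moment estimator on Pearson residuals (clamped to
±0.95); Fisher scoring iterates to `1e-10`.

*Small-sample inference is the load-bearing choice.* With eight clinics
the conventional sandwich Wald-z test is badly anticonservative: in the
package's own Monte-Carlo calibration its type-I error at nominal 0.05
is ≈ 0.16. Referring the Wald statistic to a *t* distribution with
`clinics − 4` degrees of freedom — a standard repair for GEE with few
clusters — brings it to ≈ 0.066, while the Mancl–DeRouen bias-corrected
sandwich combined with the *t* reference over-corrects (≈ 0.027). The
package therefore uses the plain sandwich with the `t(K − 4)` reference,
and the acceptance suite re-runs the null calibration (500 replicates at
8 clinics, paper-like rates) on every test run. Degenerate inputs are
flagged rather than fitted: an arm with fewer than two clinics, an empty
arm×window cell (interaction inestimable), or all-zero numerators.

**Sample size and power.** `sample_size()` is the textbook
two-proportion normal-approximation formula times a cluster design
effect `1 + (m − 1)ρ`; at 20% → 16%, α = 0.05 two-sided (two-sided is
assumed throughout), power 0.8, it returns ≈ 1,445 observations per arm,
validated against a simulation oracle of the same two-sample design.
`power_for_n()` is the prediction side; its `"did"` variant predicts the
GEE interaction test's power for the four-cell before/after design —
variance `(3 p₁q₁ + p₂q₂)/n`, noncentral-*t* with the same `K − 4`
reference the test itself uses — and matches Monte-Carlo GEE power at
the planned 12-practices-per-arm scale. At 8 clinics no closed form
tracks the simulated power well (the sandwich SE is not χ²-scaled with
so few clusters), which is worth knowing before promising power from a
formula in a small cluster trial. The returned `n_per_arm` is left
unrounded so it is exactly linear in the design effect; the integer
ceiling is reported alongside.

## Numerical and degenerate-input conventions

* Rates with zero denominators are *missing*, not zero and not errors —
  a clinic with no eligible pairs has no defined rate; probe dq10 on a
  clinic with nobody on tiotropium likewise.
* Row-level validation rejects with a per-row report (attached to the
  dataset, surfaced as a warning); unresolvable foreign keys are hard
  errors naming the offending ids. Birth dates are exempt from load-time
  date validation because one probe's subject is precisely the invalid
  birth dates present in the data.
* ICD-9 prefixes match the literal stored string — dots are not
  stripped — and the shipped fixtures carry dotted prefixes where the
  stored codes are dotted. One convention, stated loudly, beats a
  clever normalizer silently disagreeing with the data.
* All generator randomness flows from one seed; identical configurations
  give byte-identical CSV output, and the caller's RNG state is
  restored.

## Problem sizes in the shipped tests

The suite runs engine-vs-brute-force equivalence on 25 random
200-patient clinics, knob recovery at 5,000 patients per clinic
(binomial 3-SE bands computed from realized denominators), GEE null
calibration on 500 counts-level replicates at 8 clinics, and power
consistency on 300 replicates at 12 clinics per arm — sizes chosen so
the full suite exercises every claim in under a minute while keeping
Monte-Carlo bands meaningfully narrow.

## Known limitations

* The shipped rule content is representative, not authoritative; its
  clinical fidelity is explicitly out of scope and the 40-rule count is
  a library property, not a clinical claim.
* The generator's null has no intracluster correlation beyond what the
  shared knobs induce; the GEE's exchangeable structure is therefore
  exercised mostly near α = 0. Real clinics cluster harder.
* `NOT`-based criteria interact with data quality in the opposite
  direction from positive criteria: missing documentation *creates*
  fires instead of suppressing them. The library contains one such rule;
  interpret its rate accordingly.
* Aggregate answers are conserved exactly, but nothing in the package
  defends against a malicious clinic misreporting its local counts; the
  contract is privacy, not Byzantine fault tolerance.
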