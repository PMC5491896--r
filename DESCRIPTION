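Package: stoppcds
Title: STOPP Prescribing Rules as EMR Decision Support: Rule Engine,
    Data-Quality Probes, and Cluster-Trial Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computable rule engine for STOPP (Screening Tool of Older
    People's Prescriptions) criteria over coded electronic medical record
    (EMR) extracts, together with the measurement and analysis apparatus of
    a pragmatic cluster randomized trial of those rules delivered as EMR
    decision support.  Provides a restricted predicate language for
    drug-disease and drug-drug prescribing criteria (deliberately excluding
    dose and duration logic), windowed potentially-inappropriate-prescription
    (PIP) rate measurement per clinic, a suite of twelve EMR data-quality
    probes (demographics, medication coding, problem-list usage and
    drug-diagnosis concordance), a privacy-preserving aggregate-only query
    contract between clinics and a central hub, a seeded synthetic EMR
    population generator that emulates the data-quality pathologies the
    probes measure, and the trial statistics: difference-in-differences
    summaries, a clinic-clustered GEE test of the intervention effect with
    small-sample inference, and cluster-design sample-size calculations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
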