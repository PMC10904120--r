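Package: cvdmicrosim
Title: Individual-Level Cardiovascular Disease Microsimulation Policy Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An individual-level cardiovascular disease (CVD) policy model.
    Annual-cycle competing-event microsimulation of seven endpoints
    (myocardial infarction, stroke, coronary revascularisation, incident
    cancer, incident diabetes, vascular and nonvascular death) driven by
    Gompertz proportional-hazards risk equations with time-updated event
    histories, integrated EQ-5D utility prediction for quality-adjusted
    life years, risk-equation estimation from individual participant data,
    baseline recalibration and external validation against observed
    cumulative incidence, bootstrap-based probabilistic sensitivity
    analysis, guideline-based statin treatment scenarios with common
    random numbers, and direct standardization of projections to a
    reference population by sex, age band and deprivation quintile.
    Includes a synthetic-data module generating cohorts, follow-up data
    from known hazards, utility surveys and reference weight tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
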