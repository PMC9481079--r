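Package: livessaved
Title: Lives-Saved Projections for Maternal, Newborn and Child Health
    Intervention Scale-Up
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Projects stillbirths and maternal, neonatal and child deaths
    under intervention-coverage scale-up scenarios, in the lives-saved
    modelling tradition used for reproductive, maternal, newborn and child
    health and nutrition (RMNCH&N) program planning and evaluation.
    Interventions act on cause-specific mortality directly through
    efficacy and affected fraction in a residual-mortality framework, or
    indirectly by shifting the prevalence of categorical risk factors
    whose states carry cause-specific relative risks.  Coverage can be
    quality-adjusted as utilization times service readiness.  Includes
    per-intervention attribution of lives saved, missed-opportunity
    ranking, input-data summaries, modeled-versus-measured comparison, a
    seeded synthetic country-profile generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
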