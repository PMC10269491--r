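Package: ironclock
Title: Composite Biological-Age Clock from Telomere Length and Iron
    Metabolism
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibration and application of a composite biological-age
    score built from relative telomere length (RTL), serum iron, total
    iron-binding capacity (TIBC), serum ferritin and chronological age.
    Biomarkers are z-score normalized against a referent population in
    two age bands, combined with a sign convention taken from their
    population age-trends, and rescaled so that the score tracks
    chronological age in the referent population; life-expectancy
    offsets adjust for the study population and for treated HIV
    infection.  Includes a synthetic-data module that emulates both a
    referent population with prescribed moments and age-slopes and an
    HIV+/HIV- cross-sectional study cohort, plus the cohort-level
    statistical analyses (normality-gated two-group tests, detection
    limit handling for plasma viral load, polynomial ferritin-age fits,
    and biological-vs-chronological age regressions by group and
    therapy regimen).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
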