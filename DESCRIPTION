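Package: nsecorr
Title: Hemolysis-Index Based Correction of Serum Neuron-Specific Enolase
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and corrects hemolysis interference on serum
    neuron-specific enolase (NSE) measurements. Quantifies the hemolysis
    index (HI) from bichromatic absorbance readings, establishes
    nonparametric (CLSI C28-A3 style) reference intervals, derives a
    straight-line NSE-increment model from red-blood-cell lysate
    spike-recovery experiments, personalizes the correction with a
    patient-specific NSE/HI ratio, validates agreement by percent-difference
    Bland-Altman limits of agreement, and routes specimens through an
    automated report-decision cascade. Includes seeded synthetic-cohort
    generators (healthy controls, the pooled-serum spiking design, and a
    paired intentional-hemolysis validation cohort) so the whole pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
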