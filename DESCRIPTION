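Package: phhquant
Title: Quantitative Analysis for a Neonatal Rat Model of Post-Hemorrhagic
    Hydrocephalus
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for quantifying intraventricular-hemorrhage outcomes in
    neonatal rodents: RGB-box pixel classification of Perls Prussian-blue
    iron staining ("blue/pink analysis") with threshold calibration,
    ventricular CSF volumetry by Cavalieri slice-area integration with a
    compartment inclusion policy, longitudinal trend regression of
    group-mean volume trajectories, and a normality- and variance-gated
    selection among parametric and nonparametric group comparisons with the
    matching post-hoc corrections. Ships seeded synthetic-data generators
    (stained-section images with known class fractions, ellipsoid ventricle
    phantoms with analytic volumes, four-group longitudinal cohorts) so the
    whole pipeline is testable without histology slides or MR scans.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    tiff,
    car,
    multcomp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
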