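Package: paleoprov
Title: Isotope-Based Provenance and Diet Analysis for Human Skeletal Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for bioarchaeological mobility and diet
    studies based on strontium (87Sr/86Sr) and light stable isotopes
    (d13C, d15N). Estimates bioavailable 87Sr/86Sr baselines from pooled
    biomineral reference samples by Gaussian kernel density estimation with
    Sheather-Jones bandwidths and 99% highest-density intervals, classifies
    buried individuals as local, mobile or migrant, summarises cohorts with
    binomial confidence intervals and minimum-frequency-of-migrants tables,
    defines common intra-populational diet variability from bone collagen,
    detects dietary outliers, compares bone and bulk-dentine collagen, and
    screens incremental dentine profiles for life-history dietary shifts.
    Includes collagen quality control, a seeded synthetic-cohort generator
    with known ground truth, and a published reference cohort shipped as a
    plain-text fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
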