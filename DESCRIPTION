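Package: odtwin
Title: Overdiagnosis in Stool-Based Cancer Screening via Digital-Twin
    Natural-History Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits overdiagnosis-embedded multi-state Markov natural-history
    models of colorectal cancer to aggregate detection-mode counts from
    stool-based screening programmes (guaiac FOBT trials and FIT service
    screening), jointly estimating the preclinical incidence rate, the
    preclinical-to-clinical progression rate (hence the mean sojourn time)
    and per-screen test sensitivity, with competing other-cause mortality.
    Estimation is by maximum likelihood and by random-walk Metropolis MCMC
    with inverse-gamma priors on transition intensities. Fitted parameters
    drive a digital-twin prediction: the expected cancer count of a virtually
    screened copy of an unscreened comparator population, from which the
    overdiagnosis proportion (S(t)/U(t) - 1) x 100% is computed with credible
    intervals, optional competing-risk adjustment, and an adenoma-removal
    extension. Includes Pearson chi-square goodness of fit by detection mode,
    an individual-level cohort simulator with true overdiagnosis labels, and a
    configuration-driven pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
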