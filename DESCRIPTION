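Package: vesselpulse
Title: Cardiovascular MR Biomarkers of Aortic Stiffness and Left-Heart Function
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cardiovascular magnetic resonance (CMR) biomarkers of
    arterial stiffness and left-heart function from flow waveforms and planar
    contours: pulse wave velocity from cross-correlation transit times,
    regional aortic and carotid distensibility from lumen area extremes and
    cuff pulse pressure, Simpson's-rule left-atrial and left-ventricular
    volumetrics with the derived atrial emptying fractions, and carotid wall
    morphometry. Includes a synthetic phantom and cohort generator with known
    ground truth, a two-group statistical layer (Mann-Whitney, Spearman,
    adult hypertension staging, a random-intercept linear mixed-effects model
    of distensibility), and an end-to-end pipeline producing cohort reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    lme4
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
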