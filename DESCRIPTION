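Package: wibstools
Title: Single-Particle Bioaerosol Classification and Hirst Comparison for the WIBS-4+
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for five-channel UV-LIF single-particle data from
    the WIBS-4+ bioaerosol sensor. Calibrates per-channel fluorescence thresholds
    from forced-trigger (particle-free) measurements, classifies particles into
    the Perring A..ABC taxonomy and the chlorophyll-band D/E/DE taxonomy, applies
    named size and intensity proxy filters for fungal spores and pollen groups,
    aggregates selections to time-binned number concentrations and normalised
    diurnal profiles, compares daily series against Hirst-style volumetric counts
    (correlation, regression, threshold escalation, high-day co-occurrence), and
    clusters fluorescent particles with k-means selected by the Calinski-Harabasz
    index. A synthetic-campaign generator with known ground truth makes every
    stage testable in the absence of released field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
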