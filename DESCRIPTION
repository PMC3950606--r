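Package: mguard
Title: Mate-Guarding Energetics from Focal Scans, GPS Tracks and Urinary
    C-Peptide
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the energetic correlates of male
    mate-guarding in group-living primates from minute-resolution focal scan
    sampling, GPS tracklogs, monthly fruit-phenology surveys and urinary
    C-peptide assays. Provides mate-guarding episode segmentation with a grace
    window, daily activity budgets, diet composition and restlessness scores,
    subsampled horizontal travel and category-based vertical locomotion rates,
    fruit-availability indexing, creatinine-indexed urinary C-peptide with
    quality filters, I&SI dominance ranking, and linear mixed models with a
    Gaussian-kernel temporal autocorrelation term, full-versus-null likelihood
    ratio tests and collinearity diagnostics. A synthetic-study generator with
    known ground truth supports end-to-end testing and power/calibration
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    car,
    geosphere,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
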