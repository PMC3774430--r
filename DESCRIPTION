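Package: ehiscore
Title: Semi-Quantitative Occupational Chemical Exposure Risk Scoring with the
    Exposure Hazard Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Exposure Hazard Index (EHI), a semi-quantitative
    control-banding-style risk score for occupational chemical exposures.
    The index is the product of a toxicity index (TI, derived from a
    chemical's occupational exposure limit), an exposure index (EI, derived
    from daily exposure duration) and a protection deficiency index (PDI,
    derived from management and engineering/PPE control profiles), summed
    over the chemicals used in an enterprise.  Provides both the original
    categorical rating tables and an expert-system-corrected continuous
    calibration fitted from panel mean ratings, enterprise and industry
    scoring, percentile-based control-priority banding, survey CSV input
    and output, a command-line interface and a seeded synthetic survey
    generator emulating a national exposure databank.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
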