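Package: blockmvpa
Title: Block-Design fMRI Simulation and Multivoxel Pattern Decoding
Version: 0.1.0
Authors@R: person("Repo", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates block-design BOLD fMRI experiments with per-block
    awareness reports and analyses them end to end: localizer GLM contrast
    z-maps, fixed-size contiguous region-of-interest growth on statistical
    maps, a pattern-preparation chain (detrend, z-score, hemodynamic lag
    shift, block averaging, per-condition global-signal subtraction,
    awareness filtering, class balancing), leave-one-session-out linear
    support-vector classification with a univariate control, and group-level
    inference (one-tailed t versus chance with family-wise Bonferroni
    correction, paired t, and 2x2 repeated-measures ANOVA). Includes a
    minimal NIfTI-1 and BIDS-style events reader/writer and a command-line
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
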