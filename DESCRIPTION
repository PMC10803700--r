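Package: petisl
Title: Insertion of Synthetic Lesions for Comparing PET Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for lesion-based comparison of
    PET scanners using insertion of synthetic lesions (ISL). Generates paired
    scan-rescan FDG-PET phantom volumes with known ground truth, inserts
    spherical lesions of controlled diameter and contrast with partial-volume
    rasterization and point-spread-function blurring, matches acquisition
    counts across a radioactive-decay delay, extracts SUVmax/SUVmean/SUVpeak,
    and computes detection statistics: relative true-positive rates with
    paired confidence intervals, exact binomial inter-observer agreement, and
    relative-difference summaries of semi-quantitative metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
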