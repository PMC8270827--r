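Package: peakstone
Title: Single-Energy CT Classification of Uric Acid Urinary Stones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative classification of urinary stones into uric acid
    (UA) and non-uric acid (non-UA) composition from non-enhanced
    single-energy CT. Extracts the peak attenuation (maxHU) and the peak
    point Laplacian (ppLapl, the difference between the peak voxel and the
    weighted mean of its 26 neighbours in a scaled Laplacian filtered
    volume) from a stone, and classifies the (maxHU, ppLapl) pair with
    rigid cutoffs, a maxHU-only cutoff, or a k-nearest-neighbour model.
    Includes diagnostic-accuracy statistics (exact binomial confidence
    intervals, McNemar's paired test, ROC/AUC), a synthetic CT phantom and
    surrogate training-set generator for validation without clinical data,
    NIfTI and CSV input/output, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
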