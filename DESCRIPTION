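Package: zfrfc
Title: BOLD Event Onset Detection and Point-Process Functional Connectivity
    via Zero-Frequency Resonator Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates temporal onsets of blood-oxygen-level-dependent (BOLD)
    events in fMRI time courses without knowledge of the experimental paradigm,
    using a zero-frequency resonator (double cumulative sum followed by
    local-mean removal) whose positive zero-crossings mark event onsets.
    Builds two point-process functional-connectivity metrics on the detected
    onsets - the conditional rate and the high-SNR-region aggregated Pearson
    correlation - alongside a z-score threshold baseline detector and plain
    full-length correlation. Includes seed-based voxel-wise connectivity
    mapping with min-max normalization, top-fraction thresholding and
    cluster-extent filtering; onset-versus-stimulus scoring (sensitivity,
    specificity, Jaccard overlap); and a synthetic BOLD generator (sparse
    impulse trains, canonical double-gamma hemodynamic response, Gaussian or
    Rician noise, two-component 2-D phantoms) so every stage can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
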