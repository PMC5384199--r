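Package: ofcnet
Title: Theta-Band Connectivity and Behavioral Analysis for Observational
    Fear Conditioning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for observational fear conditioning (OFC)
    experiments with multichannel local field potential (LFP) recordings.
    Provides shock-locked, guard-trimmed epoching of the conditioning
    session; zero-phase theta-band filtering; per-epoch cross-correlation
    network matrices across eight bilateral regions of interest; min-max
    normalized band-power spectra; quartered-session matrix-dissimilarity
    trajectories; freezing-behavior scoring with bout detection and
    outlier exclusion; amyloid plaque burden quantification from
    histology images; and the correlation statistics (Pearson, Spearman
    with exact permutation p-values, Steiger's Z for dependent
    correlations) that relate them. A synthetic-data module generates
    every input the pipeline consumes with known ground truth, so all
    stages are testable without animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    jsonlite,
    yaml,
    EBImage,
    png,
    tiff,
    tools
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
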