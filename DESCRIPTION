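Package: rtbold
Title: RT-Modulated Deconvolution Analysis of Event-Related fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for studying trial-level coupling between reaction time and
    the BOLD response in event-related fMRI. Builds canonical gamma-variate
    hemodynamic response regressors, reaction-time-scaled regressors and their
    residualized (orthogonalized) form; converts 4D runs to percent signal
    change; fits per-voxel deconvolution GLMs with motion and drift nuisances;
    performs group one-sample t-tests with Monte-Carlo cluster-extent
    thresholding and cluster reporting. Includes a synthetic multi-subject
    BOLD generator with planted task and RT-coupling effects so every stage of
    the pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    igraph,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
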