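Package: onsembles
Title: Neuronal Ensemble Detection with Activated and Inactivated Member Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised detection of neuronal ensembles from two-photon
    calcium-imaging recordings, including the neurons that are selectively
    inactivated during ensemble events. Converts raw ROI and neuropil
    fluorescence into quality-controlled binary rasters (neuropil
    normalization, PSNR-based ROI selection, morphological smoothing,
    nonnegative AR(1) spike deconvolution, PSNR-proportional binarization),
    identifies significant repeated population patterns by Jaccard/Ward
    hierarchical clustering of population vectors with surrogate-based
    significance testing, classifies neurons as onsemble, offsemble or
    nonparticipant via an Ensemble Participation Index, fits calcium-transient
    decay constants by condition, quantifies orientation selectivity
    (1-CirVar) and Gaussian tuning width, and decodes stimulus orientation
    through informedness-optimal thresholds and multiclass confusion matrices.
    A synthetic-data generator emulating orientation-tuned population spiking
    with planted ensembles, GCaMP-like transients, neuropil contamination and
    locomotion epochs makes the whole pipeline testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
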