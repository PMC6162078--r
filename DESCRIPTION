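Package: erphab
Title: Short-Term Habituation Analysis of Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterise the short-term habituation of somatosensory
    event-related potentials (ERPs) recorded under repeated stimulation at 1 Hz.
    Implements point-by-point one-sample Wilcoxon signed-rank testing with
    cluster-level permutation correction, singular value decomposition of the
    group-average trial-by-time matrix into wave components and across-trial
    habituation components with a leave-one-out noise-SVD significance
    procedure, and model-based characterisation of the amplitude decay (four
    candidate functions, BIC selection, shuffle-resampling inference). Includes
    a synthetic multi-subject epoched-EEG generator with known ground truth, a
    preprocessing chain (Butterworth filtering, epoching, baseline correction,
    artifact rejection, medio-lateral electrode flipping, block averaging), an
    HDF5 epoch container, and an end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    rhdf5,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr
Config/testthat/edition: 3
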