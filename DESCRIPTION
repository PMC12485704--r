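Package: gaussflex
Title: Protein Flexibility Prediction from Gauss-Integral Backbone Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes protein backbones as 30-component generalized Gauss-integral
    descriptors (writhe, average crossing number and higher-order chord-diagram
    correlations of the C-alpha trace), derives per-protein flexibility from
    coordinate-ensemble RMSF, and trains attention-based 1D convolutional,
    convolutional, recurrent and kernel models to classify and regress protein
    flexibility from the descriptors. Includes PCA-based structural clustering,
    a full evaluation suite (ROC/AUC with bootstrap confidence intervals,
    precision-recall, Youden threshold, calibration, Integrated Gradients
    attribution) and synthetic generators for backbones, trajectories and
    labelled descriptor sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    e1071,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
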