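Package: deepTiles
Title: Clustering-Guided Deep Networks for Histopathology Tile Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Binary (benign/malignant) classification of small RGB
    histopathology tiles with deep networks guided by unsupervised pixel
    clustering. Provides K-Means and Mean-Shift color quantization
    transforms, three network architectures (a convolutional network, a
    stacked LSTM over a reshaped pixel sequence, and a CNN-LSTM hybrid),
    softmax cross-entropy and linear soft-margin SVM decision heads, a
    synthetic two-class tile generator with controllable class imbalance,
    and the full confusion-rate / Matthews-correlation evaluation surface.
    All layer mathematics (convolution, pooling, dense, LSTM, dropout,
    Adam) is implemented in R with exact analytic parameter counting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    EBImage,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
biocViews: Classification, Clustering, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'clustering.R'
    'io.R'
    'layers.R'
    'metrics.R'
    'nn_core.R'
    'models.R'
    'train.R'
    'synthetic.R'
    'pipeline.R'
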