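Package: heartcam
Title: Heart-Sound Classification with Attention Heads and Grad-CAM
    Interpretability Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying whether spectrogram-based heart-sound
    classifiers attend to clinically meaningful parts of the heartbeat
    cycle.  Generates annotated single-cycle phonocardiogram (PCG)
    recordings with S1/systole/S2/diastole phase intervals and murmur
    classes, converts them to 224x224 mel-spectrogram images, trains
    baseline, squeeze-and-excitation and multi-head-attention classifier
    heads on a frozen convolutional backbone, computes Grad-CAM
    localization maps, and scores the alignment of the explanations with
    phase-derived ground-truth bounding boxes via a mean-IoU protocol,
    including a balanced-versus-imbalanced training comparison.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    grDevices,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
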