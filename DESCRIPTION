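Package: otoscad
Title: Shift Contrastive Anomaly Detection for Otoscopy Video Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage screening of otoscopy video sequences as an anomaly
    detection problem. A supervised single-instance detector localises the
    eardrum in each frame; a self-supervised embedder is trained on normal
    eardrum patches with a mean-shifted contrastive objective augmented by a
    distributional-shift angular loss whose negatives are color-jittered
    variants of the training patches (whole-frame, random-rectangle, or
    random-region jitter). Frames are scored by k-nearest-neighbour cosine
    distance to a bank of normal training embeddings and videos by averaging
    frame scores; an operating threshold is chosen on a validation split at a
    target sensitivity. Includes a seed-reproducible synthetic otoscopy video
    generator emulating the statistical structure the method assumes, plus
    dataset, checkpoint and report input/output and an experiment driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    png,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
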