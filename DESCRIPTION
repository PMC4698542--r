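Package: blotmc
Title: Western-Blot Densitometry, Normalization and Monte-Carlo Group Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification and inference chain for multi-group Western-blot
    panels of synaptic proteins. Provides band densitometry from gel images
    (median-surround background subtraction and width-normalized pixel
    integration), two-stage blot normalization (blot-set average and pooled
    control-sample ratio) with a loading-control quality check, contrast
    indices of receptor-subunit and excitation/inhibition balance, and a
    parametric-bootstrap Monte-Carlo comparison that tests observed group
    means against percentile confidence intervals of a simulated sampling
    distribution. A synthetic-data module generates band tables and 16-bit
    gel images with known truth so the whole pipeline is testable without
    tissue data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
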