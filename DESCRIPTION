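Package: mmiqa
Title: Main-Target Extraction and Multi-Feature Fusion Image Quality
    Assessment for Pool Scenes
Version: 0.1.0
Authors@R:
    person("Pool IQA", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Full-reference image quality assessment (MM-IQA) aimed at
    underwater swimming-pool imagery. Combines spectral-residual saliency
    ("main target" extraction) with per-pixel luminance, contrast and
    Scharr-gradient similarity maps under saliency-weighted pooling.
    Also provides JPEG distortion-database construction, differential
    mean opinion score (DMOS) arithmetic with outlier screening, a
    synthetic pool-scene fixture generator, and the standard IQA
    evaluation harness (five-parameter logistic mapping plus SROCC,
    KROCC, PLCC, RMSE and MAE). Raster codecs (PNG/JPEG/BMP) are
    delegated to a bundled Python/Pillow helper; PGM/PPM are handled
    natively.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
SystemRequirements: python (>= 3.8) with Pillow, for PNG/JPEG/BMP
    encoding and decoding
Config/testthat/edition: 3
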