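Package: lipidscreen
Title: High-Content Lipid-Droplet Screen Analysis with Robust Plate Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for microscopy-based phenotypic screens that
    score lipid-droplet accumulation per cell. Quantifies two-channel well
    images (nuclear stain for cell counts, neutral-lipid stain for droplet
    positivity), computes per-plate robust statistics (median and median
    absolute deviation) and MAD-based Z scores, and calls hits by replicate
    consensus with a cell-death exclusion. Includes a synthetic 384-well
    plate and image generator with per-cell ground truth for validation,
    CSV/TIFF interchange, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    EBImage,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
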