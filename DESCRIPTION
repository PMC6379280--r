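Package: ciliascreen
Title: Simulation and Analysis of Live-Cell High-Content Screens for Primary Cilium Disassembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated analysis of paired-run, two-channel
    high-content imaging screens of primary cilium disassembly in ciliary
    reporter cell lines. Detects nuclei and cilium objects by intensity
    thresholding with physical size filters, computes per-site and per-well
    ciliation metrics, normalizes a post-perturbation imaging run against
    the starved-vehicle baseline, flags corrupted field pairs, and calls
    disassembly-enhancing or disassembly-blocking hits with significance.
    Includes a plate simulator that renders synthetic fluorescence fields
    with full ground truth so every analysis stage can be validated without
    microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    grDevices,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
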