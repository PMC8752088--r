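Package: neurovasc
Title: Optical Imaging Spectroscopy and Neurovascular Coupling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Converts multi-wavelength cortical reflectance image stacks into
    haemoglobin concentration time series via the modified Beer-Lambert law
    with saturation-dependent path-length scaling, extracts stimulus activation
    maps and automated regions of interest, quantifies stimulus-evoked and
    cortical-spreading-depression haemodynamics, bins supra-threshold
    multi-unit activity from multichannel extracellular recordings, and fits
    the trial-wise neurovascular coupling relation between evoked neural and
    blood-volume responses. Includes a seeded synthetic forward simulator
    (evoked gamma-kernel haemodynamics, radially propagating spreading
    depression, spike-bearing voltage traces) so that every stage is testable
    end-to-end by parameter recovery without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml,
    EBImage
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
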