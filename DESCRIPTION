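Package: efferotrack
Title: Quantitative Analysis of Microglial Efferocytosis Imaging Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of time-lapse tracking data from live imaging of
    microglial efferocytosis: mean-square-displacement curves and the
    anomalous-diffusion exponent alpha for cell motility, 3D shape
    sphericity, nearest-neighbour and spatiotemporal event statistics,
    and event-aligned centrosome-phagosome geometry (alignment angles,
    circular variance, radial probability maps). Includes a synthetic
    trajectory and event generator with known ground truth so every
    analysis stage can be exercised without raw imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
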