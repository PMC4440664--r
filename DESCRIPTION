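Package: unisecr
Title: Unified Spatially Explicit Capture-Recapture and Distance Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maximum-likelihood density estimation from spatial capture
    histories, with or without supplementary observations of animal
    location. Implements a single likelihood that spans spatially
    explicit capture-recapture (SECR), distance sampling (DS) and
    mark-recapture distance sampling (MRDS), and hybrids in which noisy
    location data (estimated bearings, times of arrival, received signal
    strengths, estimated distances) supplement the capture histories.
    Provides half-normal and signal-strength-threshold detection
    functions, binary, count and multi-catch capture-history models,
    posterior estimation of animal locations with highest-density
    contours, and a full generative simulator with a replication driver
    for simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), optparse, yaml
Config/testthat/edition: 3
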