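Package: dmoct
Title: Dynamic-Contrast Microscopic OCT Processing and Corneal Phantom Simulation
Version: 0.1.0
Authors@R:
    person("dmoct", "maintainers", email = "maintainers@dmoct.invalid", role = c("aut", "cre"))
Description: Tools for dynamic-contrast microscopic optical coherence
    tomography (dmOCT) of the corneal epithelium: per-voxel temporal Fourier
    decomposition of B-scan time series into slow/medium/fast frequency bands
    rendered as RGB, motility-coefficient and circular hue-histogram metrics,
    layer thickness from region masks, and a synthetic layered-cornea speckle
    phantom with a parametric toxic-exposure time course for end-to-end
    validation of the processing chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
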