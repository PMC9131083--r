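Package: keratrack
Title: Keratin Filament Network Geometry, Flow and Traction Force Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the geometry of keratin intermediate-filament networks
    in micropatterned epithelial cells (segment length, curvature, orientation
    radial histograms and sum vectors, junction-node linking) together with
    keratin flow fields from time-lapse stacks (windowed cross-correlation
    particle image velocimetry), rotational migration of confined cell groups,
    and traction force microscopy by regularized Fourier-transform traction
    cytometry on an elastic half-space. Includes a synthetic-scene simulator
    (micropattern masks, curvilinear filament networks rendered with a
    Gaussian point-spread function and Poisson plus read noise, advected flow
    series, fiducial-bead image pairs displaced by a force-balanced traction
    field, and a photoablation scenario) so that every analysis stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
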