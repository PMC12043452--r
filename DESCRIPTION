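Package: nephrosim
Title: Multiscale Simulation and Chemotherapy Calibration for Nephroblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discretized multiscale model of Wilms' tumor (nephroblastoma)
    volume response to preoperative chemotherapy, together with a clinical
    adaptation pipeline. The cytokinetic core tracks stem, limited-mitotic-
    potential progenitor, differentiated, apoptotic and necrotic cell
    compartments through hourly mean-field transitions. The total cell-kill
    ratio of the vincristine/actinomycin regimen is calibrated per virtual
    patient by binary search against the observed tumor-volume reduction,
    virtual patients are filtered by adaptation and histology criteria, and
    the resulting parameter distributions are compared across risk groups
    with nonparametric tests. Includes readers and writers for MetaIO and
    NRRD binary tumor masks, nearest-neighbour isotropic resampling, and a
    seeded synthetic tumor-mask generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
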