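Package: creamdex
Title: Creaming-Stability Analytics for Oil-in-Water Emulsions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for predicting the creaming behaviour of
    oil-in-water food emulsions. Measures droplet diameters on micrographs
    and summarises them as Sauter mean diameters (d32) and 5-hour size
    variation rates; fits coded-factor linear models with Box-Cox power
    transforms over a 24-run mixture/process design and screens effects
    against t-value and Bonferroni limits; extracts yield values (static
    flow limits) from flow curves of plastic-type matrices; and combines
    yield stress with droplet micro-stress into a creaming index used to
    select stable formulations. Includes a synthetic-data generator for
    micrographs, flow curves and design responses so the whole pipeline is
    testable without laboratory data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    minpack.lm,
    jsonlite,
    png
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
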