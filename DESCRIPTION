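Package: bonematrix
Title: Quantitative Bone Tissue Analysis from Backscattered Electron Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative analysis of bone tissue at the material
    level: bone mineralization density distribution (BMDD) from calibrated
    quantitative backscattered electron (qBEI) images, osteocyte lacunae
    section (OLS) morphometry, and static and dynamic bone histomorphometry
    following ASBMR nomenclature, including Z-score standardization against
    normative reference tables. A seedable synthetic-image generator emulates
    mineralized-bone gray-level fields, embedded lacunae, osteoid seams and
    tetracycline label pairs with known ground truth, so that every stage of
    the pipeline can be validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png,
    EBImage,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
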