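Package: mapreclaim
Title: Digitize Choropleth Thematic Maps into GIS Class Layers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Object-based digitization of published choropleth map images:
    georeferencing from ground control points by polynomial transforms,
    multiresolution region-merging segmentation into image objects, random-forest
    classification of objects by band colour statistics, rule-based removal of
    cartographic ink (borders and labels), zonal majority-class summaries over a
    polygon unit layer, and conversion of class areas into population and density
    estimates with calibration of a free class value against a known total.
    Includes a synthetic choropleth generator with per-pixel ground truth for
    end-to-end validation, and a command-line driver binding the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    randomForest,
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    EBImage
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    optparse
Config/testthat/edition: 3
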