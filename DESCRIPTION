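Package: terroirgrid
Title: Terrain, Climate, and Soil Characterization of Viticultural Areas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A geospatial pipeline for characterizing wine-grape appellations
    (American Viticultural Areas) from gridded environmental data. Derives
    slope, aspect, and clear-sky growing-season solar insolation from a
    digital elevation model via a horizon-angle viewshed model; computes
    growing degree-days, biologically effective degree-days, frost-free
    days, and growing-season precipitation from monthly climate normals;
    aggregates SSURGO-style soil surveys to dominant-component attribute
    rasters; summarizes every surface per appellation polygon (zonal means,
    drainage-class and aspect-sector proportions, inter-appellation
    contrasts); and runs standardized principal components analysis on the
    seven-layer environmental stack. A synthetic-data module generates
    elevation-coupled climate normals, soil surveys, and zone polygons so
    the full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    sp,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
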