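Package: isotoe
Title: Nitrogen Isotope Fingerprints of Changing Nitrogen Limitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how intensifying nitrogen limitation of marine
    phytoplankton is fingerprinted by nitrogen isotopes. Implements a
    zero-dimensional water-parcel model of nitrogen uptake, recycling and
    export with open-system isotope fractionation; a Time-of-Emergence
    detector that finds when forced trends in gridded annual-mean tracer
    fields emerge from the interannual noise of a control run; an offline
    per-cell diagnostic of the biogeochemical tendency of nitrate delta15N
    from nitrification, new-production and denitrification fluxes; and a
    synthetic-field generator with known truth for validating the detector.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
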