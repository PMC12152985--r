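Package: hmisaccess
Title: Spatio-Temporal Geographic Access to Health Services from Routine HMIS Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing changing geographic access to health services
    from routine health management information system (HMIS/DHIS2) facility
    archives and ancillary geospatial layers. The package validates and repairs
    facility coordinates against administrative boundaries, derives yearly
    service-provision indicators and a spatio-temporal functional classification
    of facilities, builds multimodal friction surfaces (land cover, roads,
    water barriers, slope-moderated walking via Tobler's hiking function),
    computes least-cost travel-time surfaces to the nearest providing facility,
    projects gridded population with annual growth rates and age-sex
    proportions, and assembles population coverage by travel-time band for
    service-specific population sub-groups. A seeded synthetic-region generator
    emulates restricted routine-data archives, with ground-truth labels for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    mgcv,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
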