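Package: driftccs
Title: Arrival-Time Extraction and Collision Cross Sections from
    Multi-Field Drift-Tube Ion Mobility Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Automated extraction of ion arrival times from drift-tube ion
    mobility spectrometry-mass spectrometry (DTIMS-MS) experiments acquired
    at multiple electric fields, and calculation of collision cross sections
    (CCS) via the Mason-Schamp relation. Detected 2D peaks (m/z x arrival
    time) are scored for Gaussian shape and isotopic-envelope agreement,
    tracked across fields by K-shortest-path global data association on an
    ion transition graph, and the optimal association hypothesis is chosen
    by maximum a posteriori probability. Reduced mobility and CCS follow
    from a straight-line fit of arrival time against p/(TV). Includes a
    synthetic multi-field frame generator, SQLite-backed frame and results
    stores, a batch processor, and a CCS library exporter.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
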