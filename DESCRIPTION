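Package: tidychrom
Title: Multi-Vendor Chromatography Trace Processing, Normalization and Sharing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parses text exports from the major HPLC and FPLC vendors
    (Waters/Empower-style tab-delimited ASCII, Shimadzu sectioned ASCII,
    Agilent two-column CSV, and AKTA/UNICORN paired-column CSV with
    fraction marks) into a canonical tidy observation table, derives
    elution volume from flow rate, applies batch scaling and range-based
    normalization (maximum over a selected interval mapped to 1, optional
    minimum-to-zero), classifies runs as analytic or preparative,
    assembles and combines named experiments, renders static trace plots
    with fraction fills, and serializes experiments to a versioned JSON
    document store with a shareable URL-state codec. Includes a seeded
    synthetic chromatogram generator (Gaussian and exponentially modified
    Gaussian peaks) that emits every supported vendor dialect, so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    optparse,
    pracma,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
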