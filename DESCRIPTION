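Package: softaudit
Title: Metadata Auditing for Bacterial Transcriptomic Records in SOFT Format
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools to audit the metadata of transcriptomic repository records
    distributed in the line-oriented SOFT (Simple Omnibus Format in Text)
    dialect used by the Gene Expression Omnibus. The package parses sample,
    series and platform entities losslessly, inventories and classifies
    metadata fields against a bundled reference catalog, measures the
    structuredness of sample "characteristics" annotations under a
    word-count stringency, triages microarray samples for raw-data
    reusability from supplementary-file types and platform manufacturer,
    profiles taxonomic composition, and fits logistic and cubic growth
    models to cumulative submission series. A synthetic-corpus generator
    with a ground-truth manifest makes every stage testable without
    network access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
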