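Package: fpbench
Title: Benchmarking Platform for 2D-Fingerprint Ligand-Based Virtual Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An open benchmarking platform for ligand-based virtual screening
    with 2D molecular fingerprints. Implements the three-stage pipeline of
    scoring (similarity ranking of test molecules against query actives with
    MAX fusion), validation (AUC, enrichment factor, RIE and BEDROC early
    recognition metrics) and analysis (fingerprint ranking across targets,
    global and post-hoc pairwise Friedman tests with bootstrap maxT
    multiplicity adjustment, correlation summaries). Includes a pluggable
    fingerprint registry (circular, path-based, torsion and dictionary
    fingerprints), eight similarity measures, Bemis-Murcko scaffold analysis
    with scaffold enrichment factors, and a synthetic compound-set generator
    emulating the curation styles of public benchmark collections so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
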