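Package: gcplasma
Title: Simulation and Repertoire Analysis of Plasma-Cell Affinity Maturation
    by Differential Division
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based, discrete-time model of the germinal center (GC)
    to plasma-cell (PC) transition in a draining lymph node, in which export
    from the GC light zone is affinity-permissive while subsequent PC clonal
    expansion is proportional to the amount of T-follicular-helper help (a
    Myc proxy) each precursor historically received. The package couples the
    simulator to the single-cell B-cell-receptor analysis stack needed to
    interrogate it: heavy/light chain pairing, somatic mutation calling
    against germline, affinity-enhancing-mutation scoring, clonal grouping,
    genotype-node collapsing and composition statistics, Chao1 richness and
    clone-size statistics, division tracking by label (H2B-mCherry analog)
    dilution, a hapten-valency ELISA avidity-ratio model for serum, and
    experiment presets with standard statistical tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
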