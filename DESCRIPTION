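Package: ftmseda
Title: Exploratory Data Analysis for Formula-Assigned FT-MS Peak Data
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the exploratory analysis of Fourier-transform mass
    spectrometry (FT-MS) peak data carrying molecular-formula assignments,
    such as the output of CoreMS or any two-file (data + molecular
    identification) format. Provides a SummarizedExperiment-based container
    for peak intensities and molecular metadata, ingestion of long-format
    candidate-assignment files with confidence-score filtering and formula
    resolution, per-peak chemical properties (elemental ratios, Kendrick mass
    and defect, nominal oxidation state of carbon and Gibbs free energy of
    carbon oxidation, aromaticity index, double-bond equivalents, elemental
    composition and van Krevelen compound classes), sequential peak filters
    with retention accounting, presence/absence and Williams-corrected G-test
    comparisons of sample groups, principal coordinate analysis with
    plot-ready tables for van Krevelen, Kendrick, density, scatter and QC
    displays, formula-to-pathway mapping against local lookup tables, and a
    provenance-tracked HTML report and CSV export bundle. A synthetic-data
    generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
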