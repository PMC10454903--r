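Package: erythroflex
Title: Red Blood Cell Deformability from Shear-Flow Micrographs and
    Membrane Proteomics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@erythroflex.org",
           role = c("aut", "cre"))
Description: Quantifies red blood cell (RBC) deformability from shear-flow
    micrographs via per-cell elongation ratios (ER = a/b) and links it to
    membrane-protein abundance. Segments adherent cells, measures
    moment-based elongation, summarizes ER distributions (AER, MER, %UDFC,
    %LDFC, CV), reads MaxQuant-style label-free quantification (LFQ)
    protein tables on the Ln(LFQ) scale, screens proteins for correlation
    with deformability, splits inter-correlated protein panels, and fits
    one- and two-protein linear deformability predictors. A synthetic-data
    module renders ground-truth elliptical cell fields and simulates
    proteomics cohorts carrying a prescribed protein-AER and
    protein-protein correlation structure, so every analysis stage is
    testable without access to raw study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    MASS,
    Matrix,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
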