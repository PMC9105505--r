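Package: shp2md
Title: Post-Simulation Analysis of SHP2 N-SH2 Conformational Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for molecular-dynamics conformational
    ensembles of the SHP2 tyrosine phosphatase, centred on the closed/open
    transition of the N-SH2 domain and its stabilisation by the exon
    6-encoded (E6) region. Provides multi-model PDB trajectory I/O with
    named region selections, Kabsch superposition and RMSD/distance series,
    domain-domain interface mapping at a heavy-atom distance threshold,
    Shrake-Rupley surface areas and buried interface area, grid-based
    groove (pY peptide-binding cleft) volume, sliding-window conformer
    fraction curves with column-synchronised Gaussian deconvolution,
    cation-pi interaction detection, averaged conformer structures, the
    hypergeometric outcome test, and a synthetic-trajectory generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
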