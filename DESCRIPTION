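Package: proppd
Title: Peptide Phage Display Enrichment Analysis and Short Linear Motif
    Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for proteomic peptide phage display (ProP-PD)
    selections against a protein bait: simulation of tiled peptide
    libraries and selection sequencing runs, demultiplexing and
    translation of selection reads into peptide count tables,
    four-criteria peptide confidence calling, de novo discovery of
    degenerate short linear motifs with binomial overrepresentation
    statistics, proteome-wide motif scanning under intrinsic-disorder and
    topology filters, PTM-crosstalk proximity statistics between motif
    instances and O-GlcNAc or phosphotyrosine sites, and Shrake-Rupley
    solvent-accessible surface area with interface burial for peptide
    complex structures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    ggplot2,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
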