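Package: nppcur
Title: Neuropeptide Precursor Curation and DNA-Loss-Model Phylogenetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based purification of candidate neuropeptide precursor
    sequences (signal-peptide heuristic, dibasic cleavage-site scanning,
    pro-protein convertase scoring), motif-based classification of mature
    peptides into the LWamide, APGWamide, RPCH/AKH, ACP, CRZ and GnRH
    families, construction of virtual precursors by conserved-codon-block
    fusion under the DNA loss model, and comparison of distance phylogenies
    built under DNA-loss-model versus default alignment penalties via the
    Robinson-Foulds metric. Includes a fully deterministic synthetic-data
    generator so every stage of the pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    phangorn,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
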