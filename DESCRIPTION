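Package: cellverdict
Title: Classify Neoplastic and Stromal/Immune Cells in Whole-Tumor scRNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes neoplastic from stromal and immune cells in
    single-cell RNA-seq of whole-tumor biopsies by integrating four sources
    of evidence: large-scale copy-number variants inferred from windowed
    expression and validated against tumor/normal exome depth ratios,
    allele patterns of heterozygous germline SNVs in regions of copy-number
    loss, expressed somatic SNVs validated in exome-seq, and hierarchical
    clustering in marker-gene space. Also scores cells for G1/S and G2/M
    proliferation programs, infers candidate ligand-receptor crosstalk
    between cell populations, and ships a negative-binomial simulator with
    dropout that generates fully labelled tumor/control datasets for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
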