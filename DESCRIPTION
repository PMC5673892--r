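Package: meth450pipe
Title: Integrative Analysis of 450K Methylation Arrays: DMRs, Copy Number,
    Mutational Signatures, Deconvolution and Methylation Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale, fully testable re-implementation of an integrative
    tumor-methylome workflow for Illumina 450K-style data: aggregation of
    probe beta values to regulatory regions (promoters, CpG islands,
    CpG-island promoters, gene bodies) with combined-rank differential
    methylation calling and cross-cohort validation; copy-number inference
    from array total intensities (probe binning, exact least-squares
    changepoint segmentation, gene-level discretization) with
    permutation-based recurrence scoring; 96-channel trinucleotide mutation
    spectra and signature refitting by forward-selection non-negative least
    squares; reference-based cell-type deconvolution and LUMP-style purity;
    Euclidean methylation distances with neighbor-joining / balanced
    minimum-evolution trees; and a nine-category gene-state integration of
    copy number and promoter methylation. A synthetic-data module generates
    every pipeline input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    ape,
    jsonlite,
    yaml,
    limma
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
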