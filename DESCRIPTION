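Package: spotmut
Title: Spatially Resolved Somatic SNV Analysis for Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping somatic single-nucleotide variants (SNVs) onto
    spatial transcriptomics sections. From a Mutect2-style somatic VCF and
    per-read evidence (spot barcode, UMI, locus, allele), the package builds
    UMI-deduplicated spot-by-SNV count matrices, applies an effective-SNV
    filter (minimum unique read and spot support), normalizes per-spot
    mutational burden against total mRNA UMI, aggregates SNVs into 100-kb
    genomic windows, detects spatially correlated SNV groups via Gaussian
    spatial smoothing and Leiden community detection, quantifies spatial
    autocorrelation (Moran's I), models the distance-dependent decay of
    mutational burden at tumor margins, and enumerates mutant 8-15-mer
    peptides from exonic nonsynonymous SNVs as neoantigen candidates. A
    synthetic-section generator with ground-truth manifests makes the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    mclust,
    jsonlite,
    vcfR,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    BiocGenerics,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    ape,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
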