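Package: codonHGT
Title: Detection of Horizontal Gene Transfer Candidates from Codon Usage
    Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational archaeology of eukaryotic genomes:
    GC-normalized relative synonymous codon usage (RSCU) profiling of coding
    sequences, nearest-neighbor assignment of genes to donor species and
    taxonomic groups by codon-usage distance, rank-based and contingency-table
    enrichment statistics over orphan genes, homology-based calling of
    horizontal gene transfer (HGT) candidate classes from BLAST tabular
    results, a six-frame longest-ORF extractor for EST sequences, and a
    seeded permutation test for colocalization of candidate genes near
    retrotransposon loci. Includes seeded synthetic-data generators with
    planted ground truth for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
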