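Package: splicealign
Title: Splice-Aware Local Realignment and Somatic Indel Calling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Local realignment of short-read alignments around candidate
    indels, with full awareness of splice junctions. Reads overlapping 400 bp
    genomic windows are re-examined against locally generated candidate
    contigs; contigs are mapped by semi-global affine-gap dynamic programming
    onto enumerated transcript representations of the local reference, and
    reads are re-placed by 10-mer seeded ungapped extension when they fit a
    contig strictly better than the reference. A companion somatic indel
    caller counts realigned allele support in tumor/normal pairs, scores
    tumor enrichment with a one-sided Fisher's exact test, applies
    orientation-bias, positional-complexity, mapping-quality and tandem-repeat
    filters, and emits VCF. A deterministic fixture simulator generates
    truth-annotated references, junction files and tumor/normal read sets with
    spiked indels for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges,
    GenomicRanges,
    VariantAnnotation,
    SummarizedExperiment,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
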