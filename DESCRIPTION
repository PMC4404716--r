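Package: polymine
Title: Haplotype-Aware SNP Mining and Genotyping-Array Design for Polyploid Transcriptomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully testable implementation of a
    transcriptome-based SNP-array design pipeline for highly heterozygous
    polyploid crops such as tetraploid rose. Covers read pre-processing
    (quality/poly-A trimming, DUST low-complexity and duplicate removal,
    paired-read merging), isoform and contaminant selection of assembled
    transcripts, per-set reference construction by greedy overlap-consensus
    assembly, haplotype-cluster based reliable-SNP calling with ploidy
    ceilings, a marker filter cascade (clean flanks, strand-ambiguity,
    paralog, chloroplast, splice-junction, cross-set redundancy and probe
    similarity screens) ending in an array manifest with two probes per SNP,
    and an orthology-guided assembly of a non-redundant transcriptome
    against a guide proteome with longest-ORF calling and full-length
    flagging. A seeded synthetic-data generator plants tetraploid
    haplotypes, paralogs, splice variants, chloroplast and fungal decoys so
    that every stage can be validated against a known truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
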