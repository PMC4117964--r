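Package: iscgh
Title: In Silico Comparative Genome Hybridization from Short-Read Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers gene presence and absence between closely related
    bacterial genomes by in silico comparative genome hybridization (CGH):
    short reads from a query strain are mapped onto an annotated reference
    genome, the reference is dissected into gene and intergenic segments,
    and each segment's coverage rate (breadth of coverage) classifies it as
    present or absent (low-coverage-rate, LCR) in the query. Downstream
    analyses characterize absent-gene clusters, their flanking mobile
    elements (tRNA direct repeats, generic direct repeats via a
    Smith-Waterman local aligner, same-family insertion sequences), codon
    usage signatures of foreign origin (GC3 and the codon adaptation
    index), and expected genome sizes. A synthetic genome and read
    generator with a recorded truth manifest supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
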