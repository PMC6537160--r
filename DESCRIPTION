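Package: syntril
Title: Syntenic Homology, Variant Effects, RIL Breakpoints, and
    Expression Background Assignment for Closely Related Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of the comparative-genomics and
    comparative-transcriptomics workflow used to contrast two closely
    related, largely collinear plant genomes and a recombinant inbred
    line (RIL) derived from their parents.  Provides syntenic-block
    homolog assignment by gene-order dynamic programming with
    similarity-weighted scoring and presence/absence (PAV) and paralog
    classification; simplified codon-aware variant-effect annotation
    with missense:silent summaries and windowed SNP densities; RIL
    haplotype painting and recombination-breakpoint calling from
    windowed allele ratios; and genotype-by-time differential-expression
    testing with parental-background assignment and temporal pattern
    grouping.  A synthetic-data module generates genome pairs, RIL
    genotypes, and negative-binomial counts with recorded ground truth
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
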