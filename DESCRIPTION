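Package: glacomp
Title: Genome-Wide Locus-Allele Comparison Across Population Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds multi-allelic haplotype-block markers (SNPLDBs) from
    biallelic SNP genotypes of inbred accessions, then performs genome-wide
    locus-allele comparison (GLAC) across ordered ancestor-descendant
    population stages: classification of allele exclusion, emergence,
    restoration and locus polymorphism loss/gain ("zero/one" changes) on top
    of ordinary frequency shifts, with per-year rates, frequency-class
    cross-tables, nucleotide diversity and Weir-Cockerham FST, selective-sweep
    region calling from external per-window statistics, and sweep-overlap
    accounting. Includes a multi-stage population simulator with planted
    allele fates for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    BiocGenerics,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    VariantAnnotation,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
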