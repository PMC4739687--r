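Package: superbsa
Title: Super Bulked-Segregant Analysis of Fruit Flavor Traits with SLAF Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trait mapping for biparental melon crosses by super bulked-segregant
    analysis (super-BSA) of specific length amplified fragment (SLAF) markers.
    Provides a seeded simulator of a reference genome, two homozygous diverged
    parents, an F2 population with total-soluble-solids (TSS) and pH phenotypes,
    and pooled SLAF allele-depth tables; parental variant triage (depth and
    repeat-region SNP filters, structural-variant validation, transition and
    transversion classification, synonymous and non-synonymous annotation,
    differential-variant and polymorphic-gene extraction); in-silico
    double-enzyme digestion, identity clustering and marker typing of SLAF loci;
    per-marker bulk allele-depth ratio statistics with consecutive-marker
    candidate-region calling; chromosome anchoring of scaffold markers; and
    candidate-gene reporting by intersecting anchored markers, trait regions,
    gene models and parental polymorphisms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
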