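Package: autozyg
Title: Homozygosity Mapping and Recessive-Variant Segregation Analysis in
    Small Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: SNP-based homozygosity mapping for recessive disease loci in
    small pedigrees, with relative-consistency filtering of shared
    homozygous regions, autosomal-recessive segregation checking of
    candidate variants, exact carrier-frequency estimation in breed
    panels, and variant-consequence plus cross-species conservation
    analysis of candidate missense changes. Includes a gene-dropping
    simulator that generates pedigree SNP genotypes, control panels and
    ortholog protein sets with known ground truth, so every stage of the
    pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rlang,
    jsonlite,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
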