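Package: ailqtl
Title: QTL Fine-Mapping in Advanced Intercross Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for fine-mapping quantitative trait loci in deep
    intercross pedigrees between divergent founder populations. Provides a
    forward simulator of advanced intercross lines (AIL) with mosaic founder
    haplotype pools and multi-locus additive trait architectures, founder
    allele-frequency-differential marker selection, identity-by-descent
    painting of descendant chromatids, mixed-linear-model association with
    GRM-based variance components, EM haplotype frequency estimation with
    substitution-effect models and backward-elimination multi-locus SNP
    selection, a multi-breed haplotype-sharing scan for selected
    sub-haplotypes, and windowed selective-sweep statistics (pi, Tajima's D,
    haplotype diversity, Fst, XP-EHH).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
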