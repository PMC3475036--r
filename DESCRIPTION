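Package: poeqtl
Title: Parent-of-Origin QTL Mapping with an Orthogonal
    Additive-Dominance-Imprinting Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome scans for quantitative trait loci (QTL) with
    parent-of-origin effects in multigeneration crosses of two inbred
    lines. Simulates F0-F3 pedigrees, ordered (paternal/maternal allele)
    genotypes and trait architectures with additive, dominance,
    imprinting, family, sex, cross-direction and maternal-genetic
    components; recovers ordered genotypes from unordered calls by
    pedigree transmission; scans the genome with a linear mixed model
    using orthogonal additive/dominance/imprinting index scores and a
    family random effect; sets genome-wide significance thresholds by
    permutation; calls, names and summarises QTL; classifies imprinting
    patterns (paternal, maternal, bipolar); discriminates genomic
    imprinting from maternal genetic effects; and decomposes phenotypic
    variance into per-effect contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
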