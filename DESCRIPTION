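Package: digenicmap
Title: Digenic Genetic Mapping with Mixed Models, LD Blocks and Expression Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Kinship-aware mixed-model association scanning (EMMA restricted
    maximum likelihood with an EMMAX generalized-least-squares scan on an
    identity-by-state kinship matrix), confidence-interval linkage-
    disequilibrium block construction in the style of Gabriel et al. with
    tag-SNP selection and per-group minor-allele-frequency mapping,
    two-locus epistasis likelihood-ratio testing, digenic penetrance
    modelling, case-control genetic power via the noncentral chi-square,
    and a singular-value-decomposition expression filter with a
    permutation null. A seeded synthetic breeding-colony generator
    produces genotype, growth and expression data carrying the structure
    the pipeline assumes, so the whole analysis is testable end to end
    without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
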