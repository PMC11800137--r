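Package: pedprio
Title: Family-Based Rare-Variant Prioritization with Co-Segregation and
    In-Silico Consensus Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Prioritizes candidate disease variants in multigenerational
    pedigrees segregating a dominant trait. Reads multi-sample VCF
    genotypes, 6-column PED pedigrees and per-variant annotation tables;
    filters variants by population allele frequency and protein-altering
    consequence; checks autosomal-dominant co-segregation of genotypes
    with affection status; computes a cumulative damaging score from a
    configurable registry of in-silico predictor criteria (SIFT,
    PolyPhen2, CADD, GERP++, M-CAP, LoFtool, Condel, DANN, FATHMM, LRT,
    MetaLR, MutationTaster, PROVEAN); and ranks the survivors. Includes a
    gene-dropping simulator that generates pedigrees, Mendelian
    genotypes, phenotypes under penetrance/phenocopy models, and
    predictor-score profiles, so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
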