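Package: haplogwas
Title: Haplotype-Block GWAS for Multi-Environment Yield Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype-based genome-wide association analysis for inbred-line
    yield-trial panels. Filters genotyping-by-sequencing SNP matrices, builds
    haplotype blocks from D-prime confidence intervals (Gabriel method),
    recodes blocks as multiallelic markers, tests them with a mixed linear
    model (principal components fixed, VanRaden kinship random, EMMAX-style
    REML), classifies associations as environment-specific or
    multi-environment stable, scans for two- and three-locus epistasis by
    linear regression, and summarises favorable-haplotype stacking. Includes
    a forward-in-time simulator of inbred breeding cohorts with
    multi-environment trial phenotypes so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    vcfR,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
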