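Package: rssnp
Title: Random-Set Enrichment Analysis of SNP Sets in Genome-Wide Association Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tests whether predefined SNP sets (pathways resolved to SNPs by
    positional mapping) contain more phenotype-associated SNPs than expected
    under two simultaneous null hypotheses: random selection of equally sized
    SNP sets, handled analytically through the hypergeometric distribution,
    and genotype-phenotype independence, handled by phenotype-label
    permutation. Includes single-SNP association tests under five genetic
    models (general, dominant, recessive, multiplicative, additive trend),
    marker-level quality control (Hardy-Weinberg exact test, control-group
    association, minor allele frequency), GMT/PLINK/TSV input, permutation
    FDR and FWER, permutation-block combination, and a synthetic genotype
    simulator with planted pathway signals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
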