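Package: skinclones
Title: Two-Compartment Clonal Seeding Simulation and Analysis for Cutaneous Lymphoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses the seeding of distinct skin compartments
    (epidermis, dermis) by circulating malignant T-cell clones in mycosis
    fungoides. Provides a generative simulator of lesions under two competing
    models (independent seeding of each compartment versus gradual infiltration
    of the epidermis from the dermis) with neutral branched subclonal evolution,
    multinomial sampling of TCR-beta clonotype repertoires and binomial sampling
    of somatic variant allele depths; and the matching analysis chain: tumor
    cell fraction (TCF) matched counting of neoplastic clonotypes, compartment
    and blood clonotype overlap, non-synonymous mutation counts and
    cross-compartment overlap, driver-gene classification (missense versus
    damaging), copy-number and purity adjusted cellular prevalence, binomial
    mixture subclone clustering with BIC model selection, constraint-based
    subclone tree reconstruction with stem/clade partition, and a rule-based
    seeding-model verdict.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
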