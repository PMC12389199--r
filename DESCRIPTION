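Package: pgxconcord
Title: Pharmacogenetic Phenotype Translation and Treatment-Response
    Concordance for CYP2C19 and CYP2D6
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Translates CYP2C19 and CYP2D6 star-allele diplotypes (including
    copy-number and hybrid tandem alleles) to metabolizer phenotypes using
    allele-function tables and the CYP2D6 activity score, applies a curated
    CPIC/DPWG guideline knowledge base to determine dosing actionability for
    twelve pharmacogenetically guided psychotropic medications, adjudicates
    whether reported adverse drug reactions and treatment inefficacies are
    consistent with metabolizer phenotypes, and aggregates results at the
    medication and participant level. Includes a Hardy-Weinberg cohort
    simulator and a deterministic reference cohort so every pipeline stage
    is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
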