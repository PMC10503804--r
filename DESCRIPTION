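Package: chipmod
Title: Inflammatory Gene Modifier Scan for CHIP-Associated Cardiovascular Risk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds genotype-based predicted gene-expression scores from
    cis-eQTL summary statistics by pruning and thresholding with grid tuning,
    annotates clonal hematopoiesis of indeterminate potential (CHIP) carrier
    status from somatic variant calls, and runs a stratified proportional-hazards
    carry-forward/interaction scan with Benjamini-Hochberg false discovery
    control to discover inflammatory-gene modifiers of CHIP-associated
    cardiovascular risk.  Ships a synthetic biobank cohort generator
    (LD-structured genotypes, sparse cis-eQTL architectures, CHIP carriers with
    realistic variant allele fractions, and survival outcomes with planted
    interaction effects) so the whole pipeline is testable end to end without
    access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
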