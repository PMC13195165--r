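Package: armtel
Title: Chromosome Arm-Specific Telomere Length Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for analysing chromosome-specific telomere length (csTL)
    estimates derived from long-read sequencing call tables: quality
    filtering and allele collapsing into per-person, per-arm telomere
    lengths; coverage down-sampling evaluation; sequencing-depth
    principal-component and categorical batch adjustment; Gaussian linear
    mixed models with crossed random effects (individual and chromosome
    arm) for variance partitioning with likelihood-ratio tests; per-arm
    association analyses with exact one-sided binomial direction tests;
    and disease association using mean and shortest telomere length.
    Includes a calibrated synthetic-cohort generator so every stage can be
    exercised and validated without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: Matrix, stats, utils, tools, yaml
Suggests: testthat (>= 3.0.0), lme4, jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
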