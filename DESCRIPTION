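Package: engraftkit
Title: Quantifying Donor Microbiota Engraftment After Faecal Microbiota Transplantation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying engraftment of donor-derived bacterial
    species after faecal microbiota transplantation (FMT) from longitudinal
    species-level metagenomic profiles. Derives donor core microbiomes by
    prevalence filtering, defines per-recipient putatively donor-derived
    species sets, and computes three engraftment metrics - the Species
    Engraftment Index (SEI), the Species Engraftment Fraction (SEF), and a
    baseline-normalised Aitchison similarity to donor - combined into a
    total engraftment score over acute, durable, and overall study windows.
    Includes Mayo-score based clinical response classification for
    ulcerative colitis trials, the exact and permutation statistics used to
    compare engraftment across arms and donors (Fisher's exact test,
    Wilcoxon rank-sum, two-way ANOVA, PERMANOVA, diversity indices, donor
    profile clustering), and a fully deterministic synthetic FMT cohort
    simulator with known ground-truth engraftment for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    car
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
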