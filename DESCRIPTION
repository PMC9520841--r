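Package: fleamorph
Title: Dual-Evidence Species Discrimination for Ctenocephalides Fleas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Landmark-based geometric morphometrics cross-validated against
    cox1 DNA barcoding for discriminating dog flea species (Ctenocephalides
    canis and C. orientis). Reads and writes TPS landmark files, resamples
    head-outline curves into semilandmarks, performs generalized Procrustes
    analysis with tangent-space projection, Procrustes ANOVA (Goodall-style
    isotropic F tests), canonical variate analysis with Mahalanobis and
    Procrustes distance permutation tests, and two-group discriminant
    function analysis with leave-one-out cross-validation. The molecular
    side collapses cox1 amplicons into haplotypes, matches them against a
    reference haplotype panel, computes Kimura two-parameter distances and
    builds neighbor-joining/minimum-evolution trees with bootstrap support.
    Descriptive survey statistics (Wald prevalence intervals, species
    composition, sex ratios, identification-agreement contingency tables)
    and seeded synthetic-data generators for every stage are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
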