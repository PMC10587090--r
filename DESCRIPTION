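Package: pamstab
Title: Stability Analysis of PAM50 Nearest-Centroid Breast Cancer Subtyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble nearest-centroid PAM50 intrinsic subtyping with
    reference-set gene centering, second-best-subtype analysis,
    leave-one-gene-cluster-out centroid perturbation with an explicit
    subtype-switch rule, refined single-sample classification from
    perturbation-stable (K0) tumors, and survival stratification of the
    resulting groups. Includes a seeded synthetic cohort generator that
    emulates the clinical subgroup composition and subtype-dependent
    survival of a population-based breast cancer cohort, so the whole
    pipeline is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
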