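Package: SectionSymmetry
Title: Tissue Classification and Dorsoventral Symmetry Scoring of Limb
    Cross-Sections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies bilateral (dorsoventral) symmetry of tissue
    architecture in transverse histological sections of regenerating
    axolotl limbs. Provides per-sample trainable pixel classification of
    trichrome-stained RGB sections into five tissue classes (background,
    cartilage, muscle, other connective tissue, epidermis) from sparse
    scribble annotations, mirror-symmetry scoring of fixed-width
    (400 micrometre) windows about a user-placed dorsoventral axis,
    a seeded synthetic section generator with a tunable asymmetry
    parameter for end-to-end validation, and the group statistics
    (Welch and paired t-tests, Fisher exact test, outcome-rate tables)
    used to compare regenerated limbs against intact limbs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    jsonlite,
    rpart,
    withr,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
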