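Package: conformerCCS
Title: Curation and Prediction of Multiconformer Peptide Ion Collisional
    Cross Sections
Version: 0.1.0
Authors@R:
    person("conformerCCS", "Developers", email = "conformerccs@example.org",
           role = c("aut", "cre"))
Description: Tools for building multiconformer peptide ion collisional
    cross section (CCS) datasets from multi-run trapped ion mobility
    spectrometry identification tables and for training CCS predictors
    that emit two conformer-specific predictions per peptidoform-charge
    pair. Implements charge-specific between-run CCS alignment with an
    overlap gate, within-run and cross-run conformer clustering at a
    relative tolerance with recurrence filtering, atomic-composition
    peptide encoding, a two-output dense regression model with an
    assignment-aware loss and transfer learning from a single-output
    model, extracted ion mobilogram peak picking with multimodality and
    replicate order-reversal statistics, Mason-Schamp mobility/CCS
    conversion, and a fully seeded synthetic data generator with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
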