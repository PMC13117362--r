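Package: cognitrace
Title: Longitudinal Psycholinguistic Screening of Cognitive Decline from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for patient-level classification of cognitive state
    (Normal, mild cognitive impairment, Alzheimer's disease) from
    longitudinal clinical note corpora. Implements deterministic
    extraction of nine psycholinguistic biomarkers (lexical diversity,
    syntactic complexity, discourse coherence), patient-specific clinical
    concept co-occurrence graphs with a GraphSAGE-style encoder, a
    hierarchical temporal encoder (bidirectional LSTM with additive
    attention), gated cross-modal fusion with a contrastive progression
    objective, leakage-safe patient-level splitting and Monte Carlo
    cross-validation, permutation and truncation stress tests, and a
    calibrated synthetic longitudinal corpus generator used as the test
    substrate in place of restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
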