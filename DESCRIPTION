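Package: phfcorr
Title: Correlation Coefficients and Group Decision Making for
    Probabilistic Hesitant Fuzzy Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for probabilistic hesitant fuzzy sets (PHFSs): score and
    deviation functions, canonical ordering with pessimistic length
    alignment, information-energy correlation coefficients and their
    weighted forms, and two baseline correlation families
    (mean/variance and plain hesitant-fuzzy) for comparison. Includes a
    complete correlation-based multi-criteria group decision-making
    pipeline that converts experts' linguistic evaluations (Saaty 1-9
    scale) into a probabilistic hesitant fuzzy group decision matrix and
    ranks alternatives by weighted correlation with an ideal
    alternative, with built-in worked examples, JSON/CSV serialization,
    a seeded random generator for property testing, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
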