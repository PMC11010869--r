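Package: onconotes
Title: Lexicon and Embedding Based Screening of Psycho-Oncology Patient Notes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for computer-aided screening of free-text patient notes in
    psycho-oncology. Implements word-class frequency statistics (adjective
    saturation, verb tenses, possessive "my" in a body context), hybrid
    sentiment polarity combining a polarity lexicon with a small recurrent
    sequence classifier, identification of areas of difficulty (body image,
    self-esteem, pain) via latent semantic analysis and a relative-difference
    rule, five-emotion intensity profiles with affective-lexicon expansion
    through embedding centroids and k-nearest neighbours, and method-versus-
    expert agreement statistics (Cohen's kappa). Ships a synthetic-corpus
    generator with planted ground truth so every component can be exercised
    and validated without access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
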