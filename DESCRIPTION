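Package: duallex
Title: Task-Driven Specialization in Dual-Stream Spoken Word Recognition Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying why sound-to-articulation ("dorsal") and
    sound-to-meaning ("ventral") mappings of spoken words favour different
    featural representations. Generates a synthetic morphologically
    structured spoken-word corpus (parametric multi-talker speech, slot-based
    phonological targets, part-of-speech-structured co-occurrence semantics),
    converts audio to cochleagrams through an ERB-spaced half-cosine
    filterbank, trains masked LSTM networks on identical acoustic input with
    dorsal, ventral, or fused targets, and provides the downstream analyses:
    cosine-similarity word identification, agglomerative decoding of onset
    and part-of-speech classes scored with adjusted mutual information,
    phoneme/morpheme selectivity indices with dendrogram comparison by
    cophenetic correlation, and error characterization by weighted
    Levenshtein ratio and distributional-embedding cosine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    ape
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
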