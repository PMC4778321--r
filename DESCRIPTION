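Package: icd10coder
Title: Example-Based Automatic ICD-10 Coding of Chinese Diagnoses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns ICD-10 subcategory codes to short diagnostic statements by
    example-based search over a standard terminology: each candidate code is
    described by the concatenation of the terminology entries filed under it,
    and a diagnosis is mapped to the code whose description text is most
    similar under a thresholded, idf-weighted semantic text-similarity metric.
    Provides a flat (exhaustive) and a hierarchical (section, category,
    subcategory descent) encoder, four interchangeable word-to-word similarity
    backends (sememe-taxonomy shortest path, longest-common-subsequence string
    similarity, word- and character-dimension co-occurrence context vectors,
    and exact match), confidence-based triage of predictions, micro-averaged
    evaluation at the 3- and 4-digit coding levels, and seeded generators for
    synthetic terminologies, corpora, sememe taxonomies and gold-standard
    coding instances so that the full pipeline is testable without any
    external resources.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
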