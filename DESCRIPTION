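Package: tfsumr
Title: Assisted Curation of Bacterial Transcription Factor Summaries by
    Extractive Summarization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts sentences describing six transcription-factor (TF)
    properties (transcriptional activity, structural domains, evolutionary
    family, regulated processes, binding sites, transcription-unit
    organization) from sentence-segmented article collections.  Six binary
    support-vector-machine classifiers are trained from property-tagged
    manual summaries under severe class imbalance, with dictionary-based
    named-entity features, several vectorization and dimensionality-reduction
    schemes, four majority-class under-sampling techniques, and G-mean-scored
    leakage-safe stratified cross-validation.  Classified sentences are
    filtered by TF mention, de-duplicated by average-linkage clustering of
    cosine similarities, and rendered as HTML summaries with hidden redundant
    sentences and PubMed links.  Includes stop-word-free ROUGE-1 evaluation,
    property-coverage reports, and a synthetic-corpus generator so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    e1071,
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
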