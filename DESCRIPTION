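Package: privscribe
Title: Privacy-Leakage Benchmarking for LLM-Generated Ambient Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds controlled privacy benchmarks for ambient clinical
    documentation and evaluates note-generation systems against them.
    Injects third-party personal disclosures (six relationship types by
    seven information topics) into patient-clinician transcripts with
    machine-readable ground truth, drives pluggable note-generation
    backends under varied prompt conditions, detects generic, specific and
    knowing leakage through thresholded sentence-embedding similarity,
    relationship-pattern and name extraction, and keyword matching, scores
    note quality with ROUGE-1 and claim-level completeness and conciseness,
    probes privacy-norm awareness, and performs exact sign-flip permutation
    inference with Holm-Bonferroni correction and similarity-threshold
    sensitivity reanalysis. Deterministic synthetic fixtures make the whole
    pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
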