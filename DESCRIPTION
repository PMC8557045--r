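Package: herbminer
Title: Association-Rule Mining of Clinical Herbal Prescription Corpora
Version: 0.1.0
Authors@R:
    person("herbminer", "developers", email = "herbminer@example.org",
           role = c("aut", "cre"))
Description: Frequent-itemset mining and frequency profiling of traditional
    Chinese medicine prescription corpora, aimed at coronary heart disease
    case records. Implements herb use-frequency and property/taste/meridian
    profiling, Apriori frequent-itemset mining with exact supports and a
    brute-force oracle, the "Top N groups" basic-prescription extraction,
    core-prescription intersection with high-frequency herbs, and
    syndrome-filtered herbal-pair mining. Ships a calibrated synthetic
    prescription-corpus generator with planted template combinations so the
    full pipeline is testable without access to clinical records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
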