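Package: m6acs
Title: Cost-Sensitive Imbalance Learning for N6-Methyladenosine Site
    Prediction in Human mRNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts N6-methyladenosine (m6A) sites in mature mRNA
    transcripts from sequence windows centred on DRACH-motif adenines.
    Implements a 509-dimension feature space (one-hot binary, chemical
    property with density, k-mer frequencies, Shannon entropy, site
    location and SNP-variant state features), a SNP-specificity position
    selection algorithm fusing Fisher's exact test and minimum-redundancy
    maximum-relevance rankings, and a cost-sensitive gradient-boosted-tree
    classifier trained on the full imbalanced sample set.  Includes
    imbalance-ratio robustness benchmarks, per-transcript evaluation and
    a seeded synthetic-corpus generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    xgboost,
    Biostrings,
    stats,
    utils,
    graphics
Suggests:
    readxl,
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
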