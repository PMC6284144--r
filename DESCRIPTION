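Package: tweettree
Title: Hierarchical Rank-2 NMF Topic Trees and Trend Analysis for Tweet Corpora
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for infoveillance studies of short social-media documents:
    reading and validating tweet corpora, unique-tweet deduplication and
    follower-reach accounting, N-gram term-frequency matrix construction with
    Porter stemming and tf-idf weighting, hierarchical document clustering by
    recursive rank-2 nonnegative matrix factorization into binary topic trees
    with an mNDCG node-splitting score, two-timepoint topic frequency trend
    comparison, and keyword-codebook mapping of clusters to UNAIDS core action
    principles and commitment areas. Includes a synthetic tweet-corpus
    generator with planted hierarchical topic structure for end-to-end
    validation and recovery scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    mclust,
    tibble,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
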