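Package: bonescreen
Title: Signature-Reversal Screening of Compound Transcriptional Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectivity-map style in-silico drug screening. Extracts an
    up/down differential-expression signature from a two-condition
    expression matrix (pooled two-sample t-test, fold-change threshold),
    scores compound-induced transcriptional rank profiles against the
    signature with a rank-based Kolmogorov-Smirnov enrichment statistic,
    combines the up- and down-set enrichment into a per-compound bone
    score, and ranks a compound library to nominate signature-reversing
    candidates. Includes a synthetic-data generator that plants
    differentially expressed genes in expression matrices and
    signature-reversing (or signature-mimicking) compounds in rank-profile
    libraries, a permutation null for score calibration, GMT/TSV/CSV
    readers and writers, and a command-line interface over the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    optparse,
    stats,
    utils
Suggests:
    fgsea,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
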