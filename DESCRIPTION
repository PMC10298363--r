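Package: switchquant
Title: Quantitative Detection, Classification and Prioritization of Isoform Switches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects isoform switching events between two conditions (for
    example tumor and matched normal tissue) from transcript-level expression
    matrices, using the differential-transcript-usage definition of a switch:
    one transcript of a gene significantly up-used (change in isoform fraction
    above a threshold) and another significantly down-used. Each switch is then
    classified by the concordance between its transcripts' usage changes and
    their expression changes, scored by characteristic sample-level frequencies
    (how often the two transcripts swap order of prevalence) and their product,
    and run through a filter chain that shortlists concordant, frequently
    switching events. A synthetic two-condition cohort generator with planted
    switches of every concordance class provides ground truth for benchmarking
    sensitivity, false discovery rate and classification accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
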