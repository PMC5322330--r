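Package: odrstream
Title: Outlier-Filtered Hoeffding Tree Learning for Data Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Incremental classification of labeled tabular data streams with
    an interquartile-range outlier filter inside the training loop. Provides
    a Hoeffding tree learner with grace-period split attempts and adaptive
    mean-of-bounds tie-breaking, sliding-window Tukey-fence outlier detection
    with a noise-versus-rare-group disposition rule and a re-learning check,
    prequential (test-then-train) evaluation with Cohen's kappa, a seeded
    synthetic stream generator with ground-truth outlier flags, ARFF and CSV
    stream readers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    foreign,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
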