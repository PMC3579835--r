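Package: armirnet
Title: Time-Course Integration of miRNA and mRNA Expression for
    Androgen Receptor Target Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate primary microRNA targets of the androgen
    receptor (AR) and the mRNAs those microRNAs modulate, from matched
    miRNA/mRNA expression time courses measured after androgen stimulation.
    Implements detection-p-value based signal amendment and gene filtering,
    quantile normalization, DiffScore-style discretization of differential
    expression against the pre-stimulation baseline, burst detection of a
    time discriminator separating early and late response, an
    earliness-weighted Response Score for ranking AR candidate primary
    targets, and a Modulation Score combining Fisher's r-to-z transformed
    correlation with a time-lag-decomposed discrete correspondence weight,
    assessed by permutation p-values and Benjamini-Hochberg false discovery
    rates. Includes a seeded synthetic time-course generator with planted
    ground truth for calibration and power studies, and assembly of the
    resulting AR-miRNA-mRNA regulatory network.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    jsonlite,
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
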