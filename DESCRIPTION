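Package: rsalearn
Title: Representational Similarity Analysis Prediction of Novel Word Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating cross-repetition multivoxel pattern similarity
    in regions of interest to behavioral learning outcomes. Implements an
    event-related design generator with jittered inter-stimulus intervals and
    repetition-spacing constraints, Pearson pattern similarity with Fisher z
    transformation, power-law learning-curve fitting with goodness-of-fit
    filtering, between- and within-subject permutation tests, dependent
    correlation comparison with one variable in common, leave-one-out
    cross-validated prediction with relative error, item median-split
    contrasts, and a synthetic-data module that plants known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    MASS,
    RNifti,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
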