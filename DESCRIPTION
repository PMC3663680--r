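Package: metagrowth
Title: Growth-Model and Formation-Rate Estimation for Metastatic Tumours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates Gompertzian and exponential growth-model parameters
    and metastasis formation rates from longitudinal tumour volume
    measurements in an individual patient. Interval specific growth rates
    (SGR) are paired with log geometric-mean volumes; a time-eliminated
    linear regression of SGR on log volume pools all metastases of a
    patient to recover the shared Gompertz parameters without knowing
    lesion ages; per-lesion formation times follow by sliding the time
    origin of the general curve, and the exponential increase of the
    cumulative metastasis count yields the formation rate. Includes direct
    per-lesion curve fitting, a seeded cohort simulator for validation,
    file input/output and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
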