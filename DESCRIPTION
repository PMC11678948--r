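Package: spiralFS
Title: Multispiral Whale Optimization for Wrapper Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Wrapper feature selection driven by the whale optimization
    algorithm (WOA) and a multispiral variant (MSWOA) that adds adaptive
    multipopulation merging, a double-spiral exploration step, and an
    early-phase quadratic-interpolation neighbourhood search. Candidate
    subsets are scored by a k-nearest-neighbour error rate under stratified
    cross-validation combined with a subset-size penalty. Includes a
    repeated-run benchmarking harness with rank-sum significance labels,
    synthetic classification data with known informative features, and a
    wearable-sensor (IMU) fall-detection demonstration pipeline with
    time/frequency/wavelet feature extraction and an RBF-kernel SVM.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    FNN,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
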