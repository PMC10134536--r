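Package: codapen
Title: Co-Data Adaptive Penalties for High-Dimensional Prediction and Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits generalised linear and Cox models with variable-specific
    ridge penalties adapted to co-data: complementary information on the
    variables (external p-values, correlations, group memberships) rather
    than on the samples.  Per-variable normal prior variances are regressed
    on the co-data through linear, generalised additive (p-spline) or
    shape-constrained additive co-data models, and estimated by empirical
    Bayes moment estimation with a memory-lean blockwise linear system.
    Fitted adaptive ridge penalties may further be transformed to
    variable-specific elastic-net penalties through the prior variance
    function, yielding sparse variable selection.  Includes a synthetic-data
    generator and benchmark harness for co-data model comparison and
    selection benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    splines,
    Matrix,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    survival,
    withr,
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
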