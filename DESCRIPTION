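Package: cumniche
Title: Cumulative Niche Accumulation Curves for Assessing Niche Model Transferability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds niche-breadth accumulation curves over a species' native
    and alien occurrence records, together with an environmental-background
    reference curve, to decide whether the available data support niche-expansion
    comparisons and ecological niche model projection into unsampled conditions.
    Includes occurrence thinning and biogeographical classification, two-step
    variable selection (collinearity exclusion by variance inflation factor,
    then retention of variables contributing at least a threshold share to a
    presence-background model), the multiplicative range-product niche-breadth
    statistic, asymptote detection with a four-scenario outcome classification,
    sampling-bias screening diagnostics, and a seeded virtual-species simulator
    that generates complete synthetic study systems with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    glmnet,
    withr,
    rlang,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
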