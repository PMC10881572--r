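Package: ofhl
Title: The Odd Frechet Half-Logistic Distribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution functions, moments and reliability measures for the
    odd Frechet half-logistic (OFHL) lifetime distribution, a two-shape-parameter
    extension of the half-logistic model obtained through the odd Frechet-G
    transform. Provides six classical estimation methods (maximum likelihood,
    Anderson-Darling, Cramer-von Mises, maximum product of spacings, ordinary and
    weighted least squares), a goodness-of-fit battery (information criteria,
    Anderson-Darling and Cramer-von Mises statistics, Kolmogorov-Smirnov test,
    total-time-on-test transform), a Monte-Carlo engine for comparing the
    estimators by bias, mean squared error and mean relative error with rank
    aggregation, and two benchmark datasets (COVID-19 mortality rates for
    Mexico and chemotherapy survival times).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
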