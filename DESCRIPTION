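Package: ionsense
Title: Multi-Ion Quantification from Ion-Selective Electrode Arrays via
    Standard Addition and Deep Kernel Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A digital twin of a six-electrode ion-selective electrode (ISE)
    array with pH, conductivity and temperature channels, together with the
    chemometric pipeline that turns its readings into simultaneous estimates
    of eight nutrient ions (nitrate, ammonium, potassium, calcium, sodium,
    chloride, dihydrogen phosphate, magnesium) in hydroponic solutions.
    Electrode responses follow the Nikolsky-Eisenman equation with secondary-
    ion interference, Nernstian temperature scaling, session drift and
    measurement noise. Training mixtures are produced by a balanced
    fractional-factorial design generator. Raw two-phase standard-addition
    records are enriched into a 17-dimensional feature space whose difference
    block cancels session-constant drift. Three regression back ends share one
    fit/predict contract: a feed-forward neural network, Gaussian-process
    regression, and deep kernel learning (a neural feature map under a
    Gaussian-process head, trained jointly by marginal likelihood), plus a
    classical log-linear single-electrode calibration baseline. Evaluation
    utilities provide RMSE, the coefficient of determination, replicate
    coefficients of variation, k-fold cross-validation and a three-model
    comparison report.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
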