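Package: glyco
Title: Predict Glycemic Index and Glycemic Load from Macronutrient
    Composition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hybrid deterministic/empirical prediction of the glycemic
    index (GI) and glycemic load (GL) of foods, beverages and meals from
    their macronutrient composition. The GI of a product is modelled as
    the availability-weighted mean GI of its glycemic carbohydrates,
    diluted by non-glycemic nutrients (fat, protein, fibers, ash) through
    empirical GI-lowering coefficients; starch availability is the
    rapidly digestible starch fraction. Includes coefficient calibration
    by least squares on the exact linearization of the model, synthetic
    calibration panels for parameter-recovery studies, a bundled
    42-breakfast-cereal benchmark, and observed-vs-predicted agreement
    statistics with Bland-Altman limits of agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
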