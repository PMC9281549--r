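Package: opfetf
Title: Indicators for Measuring the Online Public Food Environment of
    Takeaway Food
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classifies online takeaway meals and food outlets with a
    two-level taxonomy, scores each meal's healthiness (count of
    unhealthy proxy foods) and dietary diversity (DDS), aggregates
    sales-weighted outlet impact indicators (TUHII, HII, UHII) and the
    outlet health weight, and analyses their spatial pattern with
    inverse-distance Global Moran's I, weighted quartic kernel density
    surfaces and subdistrict polygon aggregation, including a
    comparison against the traditional outlet-counting availability
    measure. Ships a seeded synthetic data generator emulating a food
    delivery platform crawl so every stage is testable without
    proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    car
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
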