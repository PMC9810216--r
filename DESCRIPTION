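Package: crcdisrupt
Title: Microsimulation of Colorectal Cancer Screening Disruptions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Person-level microsimulation of colorectal cancer natural
    history (the adenoma-carcinoma sequence) and of screening by
    colonoscopy and fecal immunochemical testing (FIT), together with a
    scenario engine for pandemic-style screening disruptions: delays,
    permanent regimen switching, long-term pauses and discontinuation.
    Scenarios are evaluated as paired counterfactuals on common random
    numbers (keyed, counter-based streams), and summarised with a
    life-years calculus (life-years lost to disruption, life-years gained
    by undisrupted screening, percent of screening benefit lost), reported
    per 1,000 persons and as life-days per person.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
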