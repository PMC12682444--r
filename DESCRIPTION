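Package: ethnotally
Title: Consensus Indices for Ethnobotanical and Ethnoveterinary Use-Report Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethnobotany built around the informant
    use report: reading long-format survey data, tallying use reports (UR),
    frequency of citation (FC) and number of uses (NU), and computing the
    standard consensus indices (use value, relative frequency of citation,
    cultural importance, informant consensus factor, fidelity level, choice
    value, relative importance). Includes reconstruction of the
    species-by-ailment report matrix from published table margins with
    cross-table consistency validation, a seeded synthetic survey generator
    with heavy-tailed species popularity, and classification of local uses
    against literature reports as novel, divergent or corroborated. Ships a
    transcription of a published ethnoveterinary survey of 200 informants
    in southern Fars, Iran, as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    stringr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
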