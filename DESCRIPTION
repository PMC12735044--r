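Package: StrainScreen
Title: Entropy-Weight TOPSIS and PCA Screening of Probiotic Strain Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduces raw bioassay readings (radical-scavenging absorbance
    triplets, standard-curve absorbances, NaOH titrations, agar-diffusion
    inhibition zones) to a strain-by-indicator decision matrix, derives
    objective indicator weights from Shannon entropy, ranks candidate
    strains by TOPSIS relative closeness to the ideal solution, and
    cross-checks the ranking with a principal-component quadrant screen.
    Includes a seeded synthetic panel generator with controllable dominance
    structure so the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
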