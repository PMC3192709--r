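Package: cctrace
Title: Co-Conversion Tract Footprints and Gain/Loss History of a Homing
    Mitochondrial Intron
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the molecular footprints left by horizontal acquisition
    of the mitochondrial cox1 group I intron in flowering plants. Provides an
    in-silico PCR/gel-sizing survey (degenerate primer matching, amplicon
    sizing, intron extraction and open-reading-frame measurement), ancestral
    exon reconstruction and diagnostic-site calling in a signed coordinate
    frame anchored at the intron insertion site, co-conversion tract (CCT)
    bound estimation with homoplasy filtering, a retroprocessing-signature
    test at C-to-U RNA editing sites, and constrained Dollo parsimony
    comparison of intron gain/loss scenarios on trees with polychotomies.
    A forward simulator of exon evolution with intron homing, co-conversion
    and retroprocessing loss supplies ground-truthed synthetic data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
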