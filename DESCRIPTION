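Package: scarkit
Title: Species-Specific SCAR Marker Design and In-Silico PCR for Herbal Authentication
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for developing species-specific SCAR (sequence-characterized
    amplified region) PCR assays from DNA-barcode panels such as rDNA-ITS.
    Starting from a labeled multi-species sequence panel it discovers diagnostic
    (species-specific) nucleotides in a multiple alignment, designs 3'-anchored
    ARMS-style primer pairs with deliberate destabilizing substitutions, screens
    them by in-silico PCR under a positional mismatch model with a 3'-clamp rule,
    validates the barcode by K2P/neighbor-joining phylogenetics with bootstrap and
    monophyly testing, and models assay sensitivity (limit of detection) and
    adulterant screening of mixed samples. Includes a seeded generator of ITS-like
    panels with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
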