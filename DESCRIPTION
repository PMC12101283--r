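Package: puredisplay
Title: Design, Quality Control and Selection Simulation for PURE Ribosome
    Display of Synthetic Nanobody Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for in vitro selection campaigns that display synthetic
    nanobody (VHH) libraries on ribosomes with a reconstituted (PURE)
    cell-free system. Builds library definitions from framework alignments
    and CDR residue-frequency tables (frequency-threshold fixing rules,
    19-residue cysteine-free randomization, exact theoretical diversity),
    models single-nucleotide-deletion synthesis errors and classifies clones
    as full-length/in-frame, scores spacer genes by windowed GC content and
    a Nussinov maximum base-pairing statistic, provides the display
    efficiency / library coverage / PCR doubling quantification arithmetic,
    simulates multi-round biopanning with binding classes, surface
    alternation, pre-incubation depletion, elution chemistry and spike-in
    tracking, and calls ELISA hits at an absorbance-ratio threshold. All
    fixtures are generated synthetically; functions take data frames and
    return tibbles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
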