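Package: hybridsnv
Title: Thermodynamic Detection of Low-Abundance Point Mutations by DNA
    Hybridization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Framework to detect low-abundance single-nucleotide variants
    from two-channel DNA hybridization data. Implements a competitive
    Langmuir intensity model with nearest-neighbor style mismatch free
    energy penalties, design of perfect-match/mismatch (PM/1MM/2MM)
    probesets around a target region, robust LOWESS reference-line
    fitting of test-versus-reference intensity scatters, the branch
    distance statistic rho = ln(I_mix/I_wt), Wilcoxon rank-sum hypothesis
    testing for each candidate mutation, and a through-origin
    concentration-profile fit that converts a rho threshold into a
    concentration limit of detection. Includes a synthetic microarray
    simulator with replicate spots, lognormal noise and additive
    background for validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
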