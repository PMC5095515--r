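Package: crowscape
Title: Decomposing Genomic Differentiation Landscapes Across Contact Zones
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed population-genetic analysis of multi-population genotype
    data in the style of genome scans across avian hybrid zones. Computes
    per-window diversity and differentiation statistics (pi, Watterson's theta,
    Tajima's D, Fay and Wu's H, Fu and Li's D, Weir-Cockerham F_ST, D_xy,
    population branch statistics, mean r2, Patterson's D), haplotype-based
    selection scans (EHH, iHH, iHS, nSL, XP-EHH with empirical frequency-bin
    standardization), and the differentiation-landscape decomposition that
    separates shared linked-selection signal from contact-zone-specific
    divergence via z-standardized F_ST and net differentiation against
    allopatric control comparisons, with outlier-peak calling and
    classification. Includes a synthetic multi-population data generator with
    planted truth (shared linked-selection landscape, divergent contact-zone
    windows, selective sweeps, gene flow) so every stage is testable without
    external data, plus Moran's I autocorrelation, correlation panels,
    recombination-by-gene-density interaction models, Mantel
    isolation-by-distance, and tension-zone selection scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml,
    jsonlite,
    geosphere,
    vegan
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
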