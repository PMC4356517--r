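Package: aluRepair
Title: Simulation and Junction Analysis of Alu-Mediated Deletion Repair Products
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a selectable Alu/Alu recombination reporter cassette carrying
    two diverged Alu elements flanking an I-SceI double-strand-break site, simulates
    the repair products such a reporter recovers (single-crossover recombination
    chimeras, complex patchy chimeras, and large NHEJ deletions with junction
    microhomology), and calls repair events back from product sequences. Includes
    the quantitative layer used to analyse such experiments: homology-interval
    mapping of crossover junctions via diagnostic sites, segment-wise expected
    counts and chi-square goodness-of-fit, pathway proportions, and colony-count
    fold-decrease arithmetic.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods,
    tools
Suggests: testthat (>= 3.0.0), optparse, withr, BiocGenerics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
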