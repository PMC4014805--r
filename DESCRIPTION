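Package: varldscan
Title: Between-Population Linkage Disequilibrium Contrast Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selection signatures by contrasting regional
    linkage disequilibrium (LD) between two populations genotyped on a common
    SNP panel. Implements per-population SNP and sample quality control,
    kinship-based classical multidimensional scaling, LD-decay curves, and a
    sliding-window scan that compares the ranked eigenvalue spectra of
    windowed signed-r2 correlation matrices (the VarLD statistic), with
    genome-wide score standardization, percentile-based signal calling,
    sweep-to-population assignment, and gene/CNV interval overlap reporting.
    Includes a two-population haplotype-mosaic genotype simulator with
    implantable selective sweeps for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
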