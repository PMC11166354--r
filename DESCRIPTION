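Package: repeatloop
Title: Tandem-Repeat-Aware Analysis of RNA-Directed DNA Methylation at a
    Maize Paramutation Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for dissecting regulatory tandem repeats such as the
    penta-repeat downstream of the maize Pl1-Rhoades allele: perfect
    tandem-array detection with a collapsed-repeat reference and coordinate
    lift-over, exact-match short-read placement with unique/multi/unmapped
    classification, 4C bait-interaction tag profiling, small-RNA cluster
    calling with size-class profiles and mutant 21-mer normalization,
    conversion-based amplicon cytosine-methylation calling, and 2^-ddCt
    quantification for qRT-PCR and MNase-qPCR. A fully seeded simulator
    generates every input the pipelines consume, with recorded ground truth
    emulating the haplotype geometry and genotype contrasts of the studied
    locus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
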