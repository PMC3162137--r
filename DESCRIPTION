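Package: regenmut
Title: Mutation, Structural-Variant and Transposon Analysis for Regenerant
    Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for detecting novel homozygous point mutations
    and short indels in plants regenerated from tissue culture, by comparing
    resequenced regenerant (R1) genomes against their clonal progenitor (P1).
    Includes mapping-quality/uniqueness read filtering, per-position pileups,
    homozygous variant calling with progenitor subtraction, mutation-spectrum
    classification (transition/transversion classes, homopolymer and
    polydinucleotide indel context, coding effect), per-site mutation-rate
    estimation with heterozygote scaling, discordant ("distant") read-pair
    detection of large insertions, inversions and translocations, and
    read-depth scanning for transposable-element amplification. A paired-end
    read simulator with planted mutation/SV/TE truth sets makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse,
    withr
Config/testthat/edition: 3
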