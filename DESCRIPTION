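Package: ltmob
Title: Quantifying Chromosomal Mobility by Lateral Transduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of horizontal gene transfer rates across
    mobile genetic elements and bacterial chromosomes. Normalises transduction
    and lysogenisation titres into per-donor transfer frequencies, scores the
    cargo capacity of transferred sequences, and combines both into a relative
    frequency of genetic mobility for ranking plasmids, phages,
    phage-inducible chromosomal islands, conjugative transposons and
    chromosomal markers on a common scale. Maps headful-packaging geometry of
    lateral transduction on circular chromosomes (attB-anchored headful
    windows, locus-to-headful assignment, single-prophage reach and
    poly-lysogen coverage) and provides a seedable stochastic simulator of
    processive headful packaging for lateral and generalised transduction.
    Includes readers for GenBank and GFF3+FASTA annotations, a synthetic
    genome and element-panel generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
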