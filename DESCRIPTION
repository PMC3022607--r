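Package: ribosplit
Title: Cryptic Species Delimitation from rDNA ITS2 Copy Variants and mtDNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for delimiting cryptic insect species from multi-marker
    molecular data: in-silico PCR-RFLP genotyping of the ribosomal DNA second
    internal transcribed spacer (ITS2), intragenomic copy-variant profiling
    with a heteroduplex-signature fixation test, alignment and haplotype
    statistics, mutational-step divergence summaries with barcode-gap
    assessment, neighbour-joining trees with bootstrap support and monophyly
    checks, sympatry-based reproductive-isolation scoring, and screening for
    compensatory base changes on ITS2 secondary structures. Includes a
    seedable simulator of rDNA spacer arrays evolving under incomplete
    concerted evolution (mutation, intrachromosomal gene conversion, tandem
    indels) together with a faster-evolving single-copy mitochondrial locus,
    so the whole pipeline can be exercised on data with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
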