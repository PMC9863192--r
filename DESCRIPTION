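Package: mitocomp
Title: Comparative Analysis of Annotated Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
                  role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated circular
    mitochondrial genomes, motivated by the extreme A+T-rich, highly
    rearranged mitogenomes of scale insects (Hemiptera: Coccoidea).
    Reads and writes GenBank flat files with canonical mitochondrial gene
    naming, computes partition-wise base composition and AT/GC strand
    skews, codon-usage-bias statistics under the invertebrate
    mitochondrial code (relative synonymous codon usage, Wright's
    effective number of codons with its mutation-only expectation curve,
    positional G+C content), fits ENC-GC3 and GC12-GC3 neutrality
    regressions partitioning mutation pressure against selection,
    estimates per-gene Ka/Ks by the Nei-Gojobori pathway method with
    Jukes-Cantor correction against a reference mitogenome, and compares
    signed circular gene orders by shared adjacencies and breakpoint
    distance.  A synthetic mitogenome and coding-sequence divergence
    simulator with known ground truth supports end-to-end testing without
    any sequence download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
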