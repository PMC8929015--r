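Package: mitocomp
Title: Comparative Analysis of Circular Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of insects, built around
    circular 1-based annotation of the 37 canonical mitochondrial genes plus
    the A+T-rich control region. Reads GenBank flat files and plain feature
    tables; computes nucleotide composition, AT/GC skew and codon usage under
    the invertebrate mitochondrial code; accounts for intergenic spacers and
    gene overlaps on the circle; classifies gene-order rearrangement types
    and computes breakpoint distances; scans gene junctions for conserved
    motifs; decomposes control regions into tandem-repeat arrays; estimates
    Ka/Ks by Nei-Gojobori counting with Jukes-Cantor correction; summarises
    intraspecies per-gene divergence; evaluates annotated tRNA cloverleaf
    structures; and simulates annotated mitogenomes with known truth for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
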