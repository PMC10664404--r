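Package: gvrepeats
Title: Interspersed Inverted-Repeat Discovery and Comparative Genomics for
    Giant Virus Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects repeat-rich regions in circular giant-virus genomes from
    genome self-alignment coverage, extracts and clusters individual inverted
    repeat units, annotates MITE-like elements (terminal inverted repeats,
    target-site duplications) and the structural grammar of alternating repeat
    families, and provides the comparative-genomics statistics built on top of
    the repeat maps: pan/core-genome rarefaction with Heaps'-law openness,
    gene-duplication fractions, relative synonymous codon usage, average
    amino-acid identity, counting-method dN/dS, and enrichment and trend tests
    for genes inside repeat-rich regions.  Includes a synthetic-genome
    generator that plants repeat regions, orthologous-group matrices, and
    base-modification tracks with known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
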