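Package: imescan
Title: Annotation of Integrative Mobilizable Elements on Circular Replicons
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Sequence-based annotation of small circular replicons that
    spread as integrative mobilizable elements (IMEs).  Implements windowed,
    length-weighted and cumulative GC-skew analysis for replication
    origin/terminus prediction; prediction of attP/attB attachment sites as
    maximal exact matches anchored at tRNA 3' termini, with a composition
    based expectation score and in-silico Campbell integration; detection of
    inverted repeats (oriT hairpins, operator sites, Tn3-family terminal
    repeats), tandem iteron arrays, DnaA-box motifs and AT-rich windows;
    delineation of composite catabolic transposons from terminal-repeat
    copies; six-frame ORF calling, GC content and coding-density statistics
    with a functional-module report; and a seeded, truth-labelled synthetic
    replicon generator so the whole pipeline is testable without external
    data.  Reads and writes FASTA, GenBank flat files, GFF3 and BED with a
    single circular-coordinate convention.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
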