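Package: ydelscan
Title: K-mer Subtraction Discovery and Dating of Y-Linked Genes from
    Deletion Mutants
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully synthetic re-implementation of the
    comparative-genomic pipeline used to isolate a gene from the
    Y-specific region of a dioecious plant by subtracting k-mers between
    a male, a female, and hermaphroditic Y-deletion mutants. Provides a
    synthetic-data generator (genomes, paired-end reads, expression read
    sets, and a sexed cross), a quality trimmer, prefix-constrained
    k-mer counting and subtraction, a miniature de Bruijn assembler, a
    seed-and-extend pseudo-mapper with coverage-ratio contig selection,
    an ungapped homology search with Karlin-Altschul E-values, an
    expression screen, an X-linkage segregation test, and
    molecular-evolution estimators (Nei-Gojobori dN/dS with Jukes-Cantor
    correction, Tajima's relative-rate test, and mutation-rate dating).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    jsonlite,
    methods,
    stats,
    stringi,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
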