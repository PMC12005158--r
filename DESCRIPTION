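Package: orgvar
Title: Point Mutation and Repeat-Mediated Recombination Analysis for Plant
    Organellar Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying mutation and structural variation in plant
    mitochondrial and plastid genomes. Implements duplex-consensus variant
    calling from tagged read families with nuclear-insertion (NUMT/NUPT)
    filtering, coverage-normalized mutation spectrum analyses (substitution
    classes, genomic regions, transcriptional strand asymmetry, trinucleotide
    and dinucleotide contexts), and classification of repeat-mediated
    recombination from split long-read alignments with per-repeat and
    genome-wide recombination frequencies and sliding-window coverage ratios.
    A synthetic-data module generates circular genomes, duplex read families,
    and long reads with fully recorded truth so every stage can be validated
    against planted events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
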