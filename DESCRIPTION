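Package: uracilome
Title: Genome-Wide Uracilation Mapping and Deaminase Strand-Bias Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of genome-wide uracilation from uracil pull-down
    sequencing (UPD-seq) of bacterial genomes expressing cytosine
    deaminases, and of the parallel analyses on tumor mutation catalogs.
    Computes the NDC2 normalized differential-coverage statistic and calls
    uracilation peaks at a sigma threshold; computes the Uracilation Index
    (UI) over IUPAC sequence contexts, stratified by replicative strand
    (lagging- vs leading-strand template), transcriptional strand, and DNA
    hairpin stem strength; scans genomes for potential stem-loop
    structures; computes context-, strand-, hairpin- and
    expression-stratified normalized mutation rates with confidence
    intervals from SNV catalogs; and simulates genomes, UPD-seq position
    tables and mutation catalogs with planted structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicAlignments,
    Rsamtools,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
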