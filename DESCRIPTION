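Package: splicewise
Title: Alternative Splicing Event Classification, Isoform Fractions and
    NMD Prediction from Assembled Transcripts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies alternative splicing events (exon skipping,
    alternative donor/acceptor sites, intron retention, alternative
    first/last exons and mutually exclusive exons) from full-length
    transcript models assembled from RNA-seq, reporting the genomic
    coordinates of each differentially spliced element. For every
    transcript the package computes isoform fraction (IF) and delta-IF
    statistics between two conditions and calls binary transcript
    switches. Open reading frames are annotated from a supplied start
    codon table, and transcripts are flagged as candidate substrates of
    nonsense-mediated decay using the 50-nt premature termination codon
    rule. Includes readers for GTF, genePred, FASTA and expression
    tables, a UCSC-browser GTF exporter with expression colour coding, a
    deterministic synthetic-data generator with planted ground truth and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
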