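Package: virodisorder
Title: Survey of Intrinsic Protein Disorder Across Viral Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for surveying predicted intrinsic protein disorder
    across annotated viral genomes. Reads GenBank flat files with CDS and
    mat_peptide features, scores per-residue disorder with a windowed
    pairwise-energy predictor (pluggable, so externally computed scores can
    be substituted), and aggregates percent disorder per protein and per
    genome. Computes nucleotide composition at all sites and at four-fold
    degenerate synonymous third positions, the fraction of the genome covered
    by overlapping reading frames, and the statistical ladder relating
    disorder to genome size, base composition, viral type, host and family:
    Spearman correlations, nested ordinary-least-squares models with the
    adjusted R-squared difference as the genome-size effect, Bonferroni
    correction, and variance attribution across predictor sets. A synthetic
    viral-genome generator with known family structure provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
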