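Package: bbrpath
Title: Pathway-Ortholog Mapping and Community Dynamics for Berberine
    Biodegradation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers candidate essential, taxon-restricted enzymes in the
    bacterial biodegradation of berberine (BBR). Aligns plant pathway
    enzymes against bacterial genomes by six-frame translation and
    affine-gap Smith-Waterman local alignment, builds an enzyme-by-genome
    presence/absence matrix at a protein-similarity threshold,
    cross-classifies presence against community-enrichment and
    isolate-culturability evidence, scans methyltransferase homolog
    alignments for the conserved glycine-rich GxGxG motif, and summarises
    the genus-level distribution of homology hits. Ships a synthetic-data
    generator producing genomes with planted orthologs, genus-abundance
    time series and degradation curves with known ground truth, so the
    whole pipeline is exercisable and testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
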