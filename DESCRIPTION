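Package: pancore
Title: Scalable Pangenome and Core Genome Inference for Prokaryotes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative genomics of bacterial and archaeal genome
    collections at and above the species level. Implements scalable
    pangenome inference (fast k-mer preclustering, profile-based
    superclustering and iterative binary splitting of gene clusters into
    orthogroups under a genome co-occurrence null model), direct core
    genome inference from seed genomes with per-profile score cutoffs,
    linear-time representative genome subsampling over (trimmed)
    core-genome average nucleotide identity, concatenated core-gene
    supermatrix construction, and pangenome statistics (gene fixation
    frequency, joint maximum-likelihood estimation of orthogroup
    prevalence and genome completeness, gene-pair precision/recall).
    Includes a synthetic proteome simulator with known orthogroup truth
    for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
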