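#' @useDynLib pancore, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats hclust cutree as.dist rpois runif setNames
#' @importFrom utils write.table head
NULL

#' Proteome: the predicted genes of one genome
#'
#' Holds the amino-acid sequences (and optionally the matching coding
#' nucleotide sequences) of all predicted genes of a single genome. Gene
#' identifiers must be unique; sequences are stored uppercased exactly as
#' read (a trailing stop `*` is kept and only stripped internally for
#' scoring).
#'
#' @slot genomeId single string identifying the genome.
#' @slot aa [Biostrings::AAStringSet] of gene amino-acid sequences, named by
#'   gene id.
#' @slot nt optional [Biostrings::DNAStringSet] of coding sequences for (a
#'   subset of) the same genes, or `NULL`.
#'
#' @exportClass Proteome
setClass("Proteome",
    representation(genomeId = "character", aa = "ANY", nt = "ANY"),
    validity = function(object) {
        msg <- character()
        if (length(object@genomeId) != 1L || !nzchar(object@genomeId))
            msg <- c(msg, "genomeId must be a single non-empty string")
        if (!is(object@aa, "AAStringSet"))
            msg <- c(msg, "aa must be an AAStringSet")
        else {
            if (length(object@aa) < 1L)
                msg <- c(msg, "a Proteome needs at least one gene")
            if (anyDuplicated(names(object@aa)))
                msg <- c(msg, "duplicate gene ids in proteome")
        }
        if (!is.null(object@nt) && !is(object@nt, "DNAStringSet"))
            msg <- c(msg, "nt must be NULL or a DNAStringSet")
        if (length(msg)) msg else TRUE
    })

#' Pangenome: assignment of genes to orthogroups
#'
#' A pangenome maps every gene to exactly one orthogroup (gene family),
#' keeping track of the genome each gene came from. The on-disk form is a
#' headerless three-column TSV (gene, genome, orthogroup).
#'
#' @slot table data.frame with character columns `gene`, `genome`,
#'   `orthogroup`; each gene appears exactly once.
#'
#' @seealso [readPangenome()], [writePangenome()], [inferPangenome()]
#' @exportClass Pangenome
setClass("Pangenome",
    representation(table = "data.frame"),
    validity = function(object) {
        tb <- object@table
        msg <- character()
        if (!identical(colnames(tb), c("gene", "genome", "orthogroup")))
            msg <- c(msg, "table must have columns gene, genome, orthogroup")
        else {
            if (anyDuplicated(tb$gene))
                msg <- c(msg, "each gene may appear only once in a pangenome")
            if (!all(vapply(tb, is.character, logical(1))))
                msg <- c(msg, "all pangenome columns must be character")
        }
        if (length(msg)) msg else TRUE
    })

#' Profile: positional residue-frequency model of a gene family
#'
#' Built from a multiple sequence alignment: per alignment column, the
#' pseudocount-smoothed frequency of each of the 20 standard residues,
#' `(count + alpha) / (nrow + 20 * alpha)`. In columns without gaps the 20
#' frequencies sum to exactly 1; in gapped columns the deficit from 1 is the
#' gap mass. Columns with >= 50% gaps are dropped from the consensus (and
#' from scoring); `keep` records which columns are retained.
#'
#' @slot orthogroupId id of the source orthogroup.
#' @slot freq 20 x L numeric matrix of residue frequencies (rows named by
#'   residue, columns = alignment columns).
#' @slot keep logical vector of length L, `TRUE` for columns with < 50% gaps.
#' @slot consensus consensus sequence over the retained columns (most
#'   frequent residue per column).
#' @slot nSeqs number of alignment rows the profile was built from.
#'
#' @exportClass Profile
setClass("Profile",
    representation(orthogroupId = "character", freq = "matrix",
                   keep = "logical", consensus = "character",
                   nSeqs = "integer"),
    validity = function(object) {
        msg <- character()
        if (nrow(object@freq) != 20L)
            msg <- c(msg, "freq must have 20 rows (standard residues)")
        if (length(object@keep) != ncol(object@freq))
            msg <- c(msg, "keep must have one entry per alignment column")
        if (nchar(object@consensus) != sum(object@keep))
            msg <- c(msg, "consensus length must equal number of kept columns")
        if (length(msg)) msg else TRUE
    })

#' CoreProfile: a Profile with a calibrated membership score cutoff
#'
#' @slot cutoff minimum local-alignment score for a sequence to be accepted
#'   as a member of the family.
#' @exportClass CoreProfile
setClass("CoreProfile", contains = "Profile",
    representation(cutoff = "numeric"),
    validity = function(object) {
        if (length(object@cutoff) != 1L || !is.finite(object@cutoff))
            "cutoff must be a single finite number" else TRUE
    })

#' ProfileDB: a collection of calibrated family profiles
#'
#' @slot profiles named list of [CoreProfile-class] objects.
#' @slot msas named list of aligned [Biostrings::AAStringSet] objects (the
#'   alignments the profiles were built from).
#' @exportClass ProfileDB
setClass("ProfileDB",
    representation(profiles = "list", msas = "list"),
    validity = function(object) {
        if (!identical(names(object@profiles), names(object@msas)))
            "profiles and msas must share the same orthogroup names" else TRUE
    })

#' SampleTrace: an ordered representative sample with novelty values
#'
#' Output of farthest-first sampling: the selected items in sampling order,
#' each with its novelty, i.e. the distance (1 - identity or 1 - ANI) to the
#' nearest previously selected item. The first item gets the sentinel
#' novelty 1. Novelty is non-increasing along the order.
#'
#' @slot trace data.frame with columns `item`, `order`, `novelty` (and
#'   optionally `species` for grouped sampling).
#' @slot nDistCalls number of distance-oracle evaluations performed.
#' @exportClass SampleTrace
setClass("SampleTrace",
    representation(trace = "data.frame", nDistCalls = "integer"),
    validity = function(object) {
        tb <- object@trace
        msg <- character()
        if (!all(c("item", "order", "novelty") %in% colnames(tb)))
            msg <- c(msg, "trace needs columns item, order, novelty")
        else if (anyDuplicated(tb$item))
            msg <- c(msg, "sampled items must be distinct")
        if (length(msg)) msg else TRUE
    })

#' PrevalenceModel: joint estimates of orthogroup prevalence and genome
#' completeness
#'
#' Fitted by [fitPrevalenceCompleteness()]: gene presence is modelled as
#' Bernoulli with success probability `c[i] * q[j]` for genome i and
#' orthogroup j. At least one completeness value is anchored at 1 for
#' identifiability.
#'
#' @slot q named numeric vector of per-orthogroup prevalences in \[0, 1\].
#' @slot c named numeric vector of per-genome completeness values in
#'   \[0, 1\], with `max(c) == 1`.
#' @slot logLik numeric vector of the log-likelihood after each sweep.
#' @exportClass PrevalenceModel
setClass("PrevalenceModel",
    representation(q = "numeric", c = "numeric", logLik = "numeric"),
    validity = function(object) {
        msg <- character()
        if (any(object@q < 0 | object@q > 1)) msg <- c(msg, "q outside [0,1]")
        if (any(object@c < 0 | object@c > 1)) msg <- c(msg, "c outside [0,1]")
        if (length(object@c) && abs(max(object@c) - 1) > 1e-8)
            msg <- c(msg, "max completeness must be anchored at 1")
        if (length(msg)) msg else TRUE
    })

#' Supermatrix: concatenated core-gene nucleotide alignment
#'
#' One aligned nucleotide row per genome, formed by horizontally
#' concatenating back-translated per-family amino-acid alignments. Each
#' block is codon-multiple in length; genomes missing a family (or holding
#' more than one copy of it) carry an all-gap block.
#'
#' @slot aln [Biostrings::DNAStringSet], one row per genome, equal widths.
#' @slot blockMap data.frame with columns `orthogroup`, `start`, `end`
#'   (1-based inclusive nucleotide coordinates of each family block).
#' @exportClass Supermatrix
setClass("Supermatrix",
    representation(aln = "ANY", blockMap = "data.frame"),
    validity = function(object) {
        msg <- character()
        if (!is(object@aln, "DNAStringSet"))
            msg <- c(msg, "aln must be a DNAStringSet")
        else if (length(object@aln) &&
                 length(unique(Biostrings::width(object@aln))) != 1L)
            msg <- c(msg, "all supermatrix rows must have equal length")
        bm <- object@blockMap
        if (nrow(bm) &&
            any((bm$end - bm$start + 1L) %% 3L != 0L))
            msg <- c(msg, "blocks must be codon-multiple in length")
        if (length(msg)) msg else TRUE
    })

#' PanParams: tuning parameters for pangenome and core inference
#'
#' @slot nReps number of representative sequences used during iterative
#'   splitting when a cluster exceeds `maxAlign` members (default 32).
#' @slot maxAlign maximum number of sequences aligned directly; larger
#'   clusters are represented by `nReps` sequences (default 512).
#' @slot nSeedGenomes number of random seed genomes for core inference
#'   (default 100).
#' @slot candidateCorePrev minimum single-copy prevalence among seed genomes
#'   for a candidate core family (default 0.90).
#' @slot finalCorePrev minimum single-copy prevalence for final core
#'   families (default 0.95).
#' @slot aniMethod `"mean"` or `"meanXX"` (e.g. `"mean90"`: trim
#'   (100-XX)/2 percent of per-gene identities from each tail).
#' @slot rngSeed integer seed used for every randomised step.
#' @slot preclusterIdentity minimum k-mer identity estimate for greedy
#'   preclustering (default 0.5).
#' @slot superclusterFrac profile-profile score threshold for merging
#'   preclusters, as a fraction of the smaller profile self-score
#'   (default 0.25: between-fragment scores of one family at genus-level
#'   divergence run around half the self-score, while unrelated profiles
#'   stay below 5%).
#'
#' @exportClass PanParams
setClass("PanParams",
    representation(nReps = "integer", maxAlign = "integer",
                   nSeedGenomes = "integer", candidateCorePrev = "numeric",
                   finalCorePrev = "numeric", aniMethod = "character",
                   rngSeed = "integer", preclusterIdentity = "numeric",
                   superclusterFrac = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@candidateCorePrev <= 0 ||
            object@candidateCorePrev > object@finalCorePrev ||
            object@finalCorePrev > 1)
            msg <- c(msg,
                "need 0 < candidateCorePrev <= finalCorePrev <= 1")
        if (object@nReps > object@maxAlign)
            msg <- c(msg, "nReps must not exceed maxAlign")
        if (object@nReps < 2L) msg <- c(msg, "nReps must be >= 2")
        if (!grepl("^mean([0-9]{2})?$", object@aniMethod))
            msg <- c(msg, "aniMethod must be 'mean' or 'meanXX'")
        if (length(msg)) msg else TRUE
    })
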