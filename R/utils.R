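# shared internals: seeded evaluation, atomic writes, scoring lookups

.pancore <- new.env(parent = emptyenv())

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    eval.parent(substitute(expr))
}

# Write via `writer(tmpPath)` then rename into place.
atomicWrite <- function(path, writer) {
    tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path)) stop("could not move temp file to ", path)
    invisible(path)
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# 128x128 substitution lookups indexed by raw character code.
aaLookup <- function() {
    if (!is.null(.pancore$aaLookup)) return(.pancore$aaLookup)
    bl <- get(utils::data("BLOSUM62", package = "Biostrings",
                          envir = environment())[1], envir = environment())
    m <- matrix(-4, 128, 128)
    chars <- rownames(bl)
    idx <- utf8ToInt(paste(chars, collapse = "")) + 1L
    m[idx, idx] <- bl[chars, chars]
    .pancore$aaLookup <- m
    m
}

ntLookup <- function() {
    if (!is.null(.pancore$ntLookup)) return(.pancore$ntLookup)
    m <- matrix(-3, 128, 128)
    nt <- c("A", "C", "G", "T")
    idx <- utf8ToInt(paste(nt, collapse = "")) + 1L
    sub <- matrix(-3, 4, 4)
    diag(sub) <- 2
    m[idx, idx] <- sub
    ni <- utf8ToInt("N") + 1L
    m[ni, ] <- 0; m[, ni] <- 0
    .pancore$ntLookup <- m
    m
}

# default gap penalties (BLAST-style; gap of length L costs open + L * ext)
AA_GAP_OPEN <- 11
AA_GAP_EXT <- 1
NT_GAP_OPEN <- 5
NT_GAP_EXT <- 2

# strip a trailing stop character for scoring purposes
stripStop <- function(x) sub("\\*$", "", x)

# coerce a list of Proteome objects (or a single Proteome) to a named list
asProteomeList <- function(proteomes) {
    if (is(proteomes, "Proteome")) proteomes <- list(proteomes)
    if (!is.list(proteomes) || !all(vapply(proteomes, is, logical(1),
                                           "Proteome")))
        stop("expected a Proteome or a list of Proteome objects")
    names(proteomes) <- vapply(proteomes, function(p) p@genomeId,
                               character(1))
    if (anyDuplicated(names(proteomes)))
        stop("duplicate genome ids among proteomes")
    proteomes[order(names(proteomes))]
}

# all amino-acid sequences of a proteome list as one named character vector,
# with a parallel genome vector; trailing stops stripped for scoring
allGenes <- function(proteomes) {
    proteomes <- asProteomeList(proteomes)
    seqs <- unlist(lapply(proteomes, function(p) {
        s <- as.character(p@aa)
        names(s) <- names(p@aa)
        s
    }), use.names = FALSE)
    ids <- unlist(lapply(proteomes, function(p) names(p@aa)),
                  use.names = FALSE)
    genomes <- rep(vapply(proteomes, function(p) p@genomeId, character(1)),
                   vapply(proteomes, function(p) length(p@aa), integer(1)))
    if (anyDuplicated(ids)) {
        d <- ids[duplicated(ids)][1]
        stop("gene id '", d, "' occurs in more than one proteome")
    }
    names(seqs) <- ids
    list(seqs = vapply(seqs, stripStop, character(1), USE.NAMES = TRUE),
         genomes = setNames(genomes, ids))
}
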