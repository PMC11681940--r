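# Fixture builders shared across the suite. Everything is generated in
# code; no files are shipped.

# A Proteome from named character vectors (aa mandatory, nt optional).
makeProteome <- function(genomeId, aa, nt = NULL) {
    aaSet <- Biostrings::AAStringSet(aa)
    ntSet <- if (is.null(nt)) NULL else Biostrings::DNAStringSet(nt)
    new("Proteome", genomeId = genomeId, aa = aaSet, nt = ntSet)
}

# Deterministic random amino-acid sequence.
randomAa <- function(n, seed) {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    withr::with_seed(seed, paste(sample(aa, n, replace = TRUE),
                                 collapse = ""))
}

# Mutate a fraction of residues of an amino-acid sequence (never to the
# original residue).
mutateAa <- function(seq, frac, seed) {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
    chars <- strsplit(seq, "")[[1]]
    withr::with_seed(seed, {
        pos <- sample(length(chars), round(frac * length(chars)))
        for (p in pos) chars[p] <- sample(setdiff(aa, chars[p]), 1)
    })
    paste(chars, collapse = "")
}

# Mutate exactly `nDiff` nucleotide positions (never to the original base).
mutateNt <- function(seq, nDiff, seed) {
    nt <- c("A", "C", "G", "T")
    chars <- strsplit(seq, "")[[1]]
    withr::with_seed(seed, {
        pos <- sample(length(chars), nDiff)
        for (p in pos) chars[p] <- sample(setdiff(nt, chars[p]), 1)
    })
    paste(chars, collapse = "")
}

randomNt <- function(n, seed) {
    withr::with_seed(seed,
        paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
              collapse = ""))
}

# Exhaustive maximin oracle: given the first pick, repeatedly select the
# item maximising the minimum distance to the current selection by direct
# enumeration (ties by smallest id).
oracleMaximin <- function(ids, D, first, k) {
    sel <- first
    nov <- 1.0
    while (length(sel) < k) {
        rest <- setdiff(ids, sel)
        minD <- vapply(rest, function(r) min(D[r, sel]), numeric(1))
        mx <- max(minD)
        cand <- sort(rest[minD >= mx - 1e-12])[1]
        sel <- c(sel, cand)
        nov <- c(nov, mx)
    }
    list(order = sel, novelty = nov)
}

# A small simulated dataset cached for the whole test run.
cachedSim <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- simulatePangenome(nGenomes = 10, nCoreFamilies = 25,
                                        nAccessoryFamilies = 15,
                                        targetIdentity = 0.9, seed = 101)
        cache
    }
})
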