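# ANI between genomes, trimmed variants, and representative genome
# sampling. Fixtures use equal-length nucleotide genes with an exact
# number of substitutions, so per-gene identities are known in closed
# form.

# two-genome fixture: gene i of genome B differs from genome A at
# `diffs[i]` of 300 positions
aniFixture <- function(diffs, seed = 4000) {
    n <- length(diffs)
    baseNt <- vapply(seq_len(n), function(i) randomNt(300, seed + i),
                     character(1))
    mkGenome <- function(id, nts) {
        names(nts) <- paste0(id, "_g", seq_len(n))
        aaSet <- as.character(Biostrings::translate(
            Biostrings::DNAStringSet(nts), no.init.codon = TRUE))
        names(aaSet) <- names(nts)
        makeProteome(id, aaSet, nts)
    }
    A <- mkGenome("A", baseNt)
    B <- mkGenome("B", vapply(seq_len(n), function(i)
        mutateNt(baseNt[i], diffs[i], seed + 100 + i), character(1)))
    rows <- rbind(
        data.frame(gene = names(pancore::ntSeqs(A)), genome = "A",
                   orthogroup = sprintf("F%03d", seq_len(n))),
        data.frame(gene = names(pancore::ntSeqs(B)), genome = "B",
                   orthogroup = sprintf("F%03d", seq_len(n))))
    list(pg = Pangenome(rows), proteomes = list(A, B))
}

test_that("ANI of a genome with itself is 1 and ANI is symmetric", {
    fx <- aniFixture(rep(3, 5))
    expect_equal(as.numeric(pairwiseAni(fx$pg, fx$proteomes, "A", "A")), 1)
    ab <- pairwiseAni(fx$pg, fx$proteomes, "A", "B")
    ba <- pairwiseAni(fx$pg, fx$proteomes, "B", "A")
    expect_equal(as.numeric(ab), as.numeric(ba))
    expect_equal(as.numeric(ab), 297 / 300)
})

test_that("mean90 trims one gene from each tail per the stated rule", {
    # identities: one low outlier (0.5), eighteen at 0.99, one at 0.999
    diffs <- c(150, rep(3, 18), 0)
    fx <- aniFixture(diffs)
    plain <- as.numeric(pairwiseAni(fx$pg, fx$proteomes, "A", "B",
                                    method = "mean"))
    trimmed <- as.numeric(pairwiseAni(fx$pg, fx$proteomes, "A", "B",
                                      method = "mean90"))
    # floor(0.05 * 20) = 1 from each tail: the middle 18 genes, each at
    # exactly 297/300 matches
    expect_equal(trimmed, 0.99)
    # the untrimmed mean is dragged down by the outlier gene
    expect_lt(plain, 0.985)
})

test_that("one horizontally-transferred outlier shifts cANI but leaves
           mean90 tcANI unchanged to 4 decimals", {
    clean <- aniFixture(rep(3, 20), seed = 4200)
    dirty <- aniFixture(c(150, rep(3, 19)), seed = 4200)
    cleanMean <- as.numeric(pairwiseAni(clean$pg, clean$proteomes,
                                        "A", "B"))
    dirtyMean <- as.numeric(pairwiseAni(dirty$pg, dirty$proteomes,
                                        "A", "B"))
    cleanTrim <- as.numeric(pairwiseAni(clean$pg, clean$proteomes,
                                        "A", "B", method = "mean90"))
    dirtyTrim <- as.numeric(pairwiseAni(dirty$pg, dirty$proteomes,
                                        "A", "B", method = "mean90"))
    expect_gt(abs(dirtyMean - cleanMean), 0.01)
    expect_equal(round(dirtyTrim, 4), round(cleanTrim, 4))
})

test_that("genomes without shared single-copy families give NA with a
           warning", {
    rows <- data.frame(gene = c("a1", "b1"), genome = c("A", "B"),
                       orthogroup = c("F1", "F2"))
    fx <- aniFixture(rep(3, 2))
    expect_warning(
        res <- pairwiseAni(Pangenome(rows), fx$proteomes, "A", "B"),
        "no shared")
    expect_true(is.na(res))
})

test_that("sampling picks one genome per clonal cluster", {
    # three clusters of near-identical genomes, distant between clusters
    mkCluster <- function(tag, seedBase) {
        base <- vapply(1:5, function(i) randomNt(300, seedBase + i),
                       character(1))
        lapply(1:3, function(j) {
            nts <- vapply(base, function(x) mutateNt(x, 1, seedBase +
                          10 * j), character(1))
            names(nts) <- sprintf("%s%d_g%d", tag, j, 1:5)
            aa <- as.character(Biostrings::translate(
                Biostrings::DNAStringSet(nts), no.init.codon = TRUE))
            names(aa) <- names(nts)
            makeProteome(sprintf("%s%d", tag, j), aa, nts)
        })
    }
    proteomes <- c(mkCluster("x", 5000), mkCluster("y", 6000),
                   mkCluster("z", 7000))
    rows <- do.call(rbind, lapply(proteomes, function(p)
        data.frame(gene = names(ntSeqs(p)), genome = genomeId(p),
                   orthogroup = sprintf("F%d", 1:5))))
    pg <- Pangenome(rows)
    tr <- sampleTrace(sampleGenomes(pg, proteomes, k = 3, seed = 2))
    expect_setequal(substr(tr$item, 1, 1), c("x", "y", "z"))
    expect_true(all(diff(tr$novelty) <= 1e-12))
})

test_that("a maximum-identity stop excludes exact duplicates", {
    base <- vapply(1:5, function(i) randomNt(300, 8000 + i), character(1))
    mk <- function(id, nts) {
        names(nts) <- paste0(id, "_g", 1:5)
        aa <- as.character(Biostrings::translate(
            Biostrings::DNAStringSet(nts), no.init.codon = TRUE))
        names(aa) <- names(nts)
        makeProteome(id, aa, nts)
    }
    proteomes <- list(mk("A", base), mk("B", base),  # B duplicates A
                      mk("C", vapply(base, function(x)
                          mutateNt(x, 30, 8100), character(1))))
    rows <- do.call(rbind, lapply(proteomes, function(p)
        data.frame(gene = names(ntSeqs(p)), genome = genomeId(p),
                   orthogroup = sprintf("F%d", 1:5))))
    pg <- Pangenome(rows)
    tr <- sampleTrace(sampleGenomes(pg, proteomes,
                                    maxIdentity = 0.9999, seed = 1))
    expect_length(tr$item, 2L)
    expect_false(all(c("A", "B") %in% tr$item))
})

test_that("per-species sampling honours the cap within each species", {
    fxs <- lapply(1:2, function(s) {
        base <- vapply(1:5, function(i) randomNt(300, 9000 + 100 * s + i),
                       character(1))
        lapply(1:3, function(j) {
            nts <- vapply(base, function(x)
                mutateNt(x, 5 * j, 9000 + 100 * s + 10 * j), character(1))
            names(nts) <- sprintf("sp%d_%d_g%d", s, j, 1:5)
            aa <- as.character(Biostrings::translate(
                Biostrings::DNAStringSet(nts), no.init.codon = TRUE))
            names(aa) <- names(nts)
            makeProteome(sprintf("sp%d_%d", s, j), aa, nts)
        })
    })
    proteomes <- c(fxs[[1]], fxs[[2]])
    rows <- do.call(rbind, lapply(proteomes, function(p)
        data.frame(gene = names(ntSeqs(p)), genome = genomeId(p),
                   orthogroup = sprintf("F%d", 1:5))))
    pg <- Pangenome(rows)
    species <- setNames(sub("_[0-9]+$", "", vapply(proteomes, genomeId,
                                                   character(1))),
                        vapply(proteomes, genomeId, character(1)))
    tr <- sampleTrace(sampleGenomes(pg, proteomes, speciesMap = species,
                                    perSpeciesCap = 2, seed = 1))
    expect_equal(unname(table(tr$species)), c(2L, 2L),
                 ignore_attr = TRUE)
})

test_that("core subsets are seeded and clamp to the family count", {
    sim <- cachedSim()
    s1 <- subsetCore(sim$truth, nGenes = 10, seed = 5)
    s2 <- subsetCore(sim$truth, nGenes = 10, seed = 5)
    expect_identical(s1, s2)
    expect_length(s1, 10L)
    all <- subsetCore(sim$truth, nGenes = 10000)
    expect_identical(all, orthogroupIds(sim$truth))
})
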