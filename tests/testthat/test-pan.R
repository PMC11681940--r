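# Binary splitting and full pangenome inference: null-model arithmetic
# against a Monte-Carlo permutation oracle, split proposals against a
# brute-force partition oracle, and partition/determinism properties.

# Monte-Carlo oracle for the expected co-occurrence: randomly reassign the
# parent's genes to sides of the observed sizes and count genomes holding
# both sides.
mcExpected <- function(genomes, a, nDraw, seed) {
    n <- length(genomes)
    withr::with_seed(seed, {
        draws <- vapply(seq_len(nDraw), function(i) {
            sideA <- sample(n, a)
            length(intersect(unique(genomes[sideA]),
                             unique(genomes[-sideA])))
        }, numeric(1))
    })
    c(mean = mean(draws), se = sd(draws) / sqrt(nDraw))
}

test_that("strictly single-copy splits sit at the 0/0 boundary and are
           rejected", {
    cl <- data.frame(gene = sprintf("g%02d", 1:10),
                     genome = sprintf("G%02d", 1:10))
    v <- evaluateSplit(cl[1:5, ], cl[6:10, ])
    expect_equal(v$observed, 0)
    expect_equal(v$expected, 0)
    expect_false(v$accepted)
    # unequal sizes, still all k_g = 1
    v2 <- evaluateSplit(cl[1:7, ], cl[8:10, ])
    expect_equal(v2$expected, 0)
    expect_false(v2$accepted)
})

test_that("clean paralogs (one A and one B gene per genome) are
           accepted", {
    genomes <- sprintf("G%02d", 1:8)
    subA <- data.frame(gene = paste0("a", 1:8), genome = genomes)
    subB <- data.frame(gene = paste0("b", 1:8), genome = genomes)
    v <- evaluateSplit(subA, subB)
    expect_equal(v$observed, 8)
    expect_gte(v$observed, v$expected)
    expect_true(v$accepted)
})

test_that("evaluateSplit validates its inputs", {
    cl <- data.frame(gene = c("g1", "g2"), genome = c("A", "B"))
    expect_error(evaluateSplit(cl, cl), "overlap")
    expect_error(evaluateSplit(cl[0, ], cl), "non-empty")
})

test_that("expected co-occurrence matches a permutation Monte-Carlo
           oracle on random clusters", {
    for (rep in 1:8) {
        withr::with_seed(5000 + rep, {
            n <- sample(6:40, 1)
            genomes <- sample(sprintf("G%02d", 1:sample(3:12, 1)), n,
                              replace = TRUE)
            a <- sample(seq_len(n - 1), 1)
        })
        cl <- data.frame(gene = sprintf("g%02d", 1:n), genome = genomes)
        v <- evaluateSplit(cl[1:a, , drop = FALSE],
                           cl[(a + 1):n, , drop = FALSE])
        mc <- mcExpected(genomes, a, nDraw = 10000, seed = 5100 + rep)
        expect_lt(abs(v$expected - mc["mean"]), 3 * max(mc["se"], 1e-9))
    }
})

test_that("split proposals separate two sequence types (brute-force
           2-partition oracle)", {
    x <- randomAa(60, 600)
    y <- randomAa(60, 601)
    seqs <- c(g1 = x, g2 = x, g3 = y, g4 = y)
    cl <- data.frame(gene = names(seqs),
                     genome = c("A", "B", "A", "B"))
    sp <- proposeSplit(cl, seqs, PanParams())
    sides <- sort(vapply(list(sp$A$gene, sp$B$gene), paste, character(1),
                         collapse = ","))
    expect_identical(sides, c("g1,g2", "g3,g4"))
    # brute-force: among all 2-partitions, g1,g2|g3,g4 maximises total
    # within-side identity
    parts <- list(list(c("g1","g2"), c("g3","g4")),
                  list(c("g1","g3"), c("g2","g4")),
                  list(c("g1","g4"), c("g2","g3")))
    within <- vapply(parts, function(p) sum(vapply(p, function(side) {
        pr <- combn(side, 2)
        sum(vapply(seq_len(ncol(pr)), function(i)
            globalAlign(seqs[[pr[1, i]]], seqs[[pr[2, i]]])$identity,
            numeric(1)))
    }, numeric(1))), numeric(1))
    expect_equal(parts[[which.max(within)]][[1]], c("g1", "g2"))
})

test_that("a 2-gene cluster splits into singletons", {
    seqs <- c(g1 = randomAa(40, 610), g2 = randomAa(40, 611))
    cl <- data.frame(gene = c("g1", "g2"), genome = c("A", "B"))
    sp <- proposeSplit(cl, seqs, PanParams())
    expect_equal(nrow(sp$A), 1L)
    expect_equal(nrow(sp$B), 1L)
})

test_that("identical sequences still yield two non-empty sides, left for
           the null model to reject", {
    s <- randomAa(40, 620)
    cl <- data.frame(gene = paste0("g", 1:4),
                     genome = paste0("G", 1:4))
    sp <- proposeSplit(cl, setNames(rep(s, 4), cl$gene), PanParams())
    expect_gt(nrow(sp$A), 0)
    expect_gt(nrow(sp$B), 0)
    expect_false(evaluateSplit(sp$A, sp$B)$accepted)
})

test_that("single-copy families stay whole through splitting", {
    sim <- cachedSim()
    tb <- panTable(sim$truth)
    # restrict to families that are single-copy everywhere
    copies <- table(tb$orthogroup, tb$genome)
    sco <- rownames(copies)[apply(copies <= 1, 1, all)]
    pg <- inferPangenome(sim$proteomes, PanParams(rngSeed = 5))
    predOf <- setNames(panTable(pg)$orthogroup, panTable(pg)$gene)
    for (f in sco) {
        members <- tb$gene[tb$orthogroup == f]
        expect_length(unique(predOf[members]), 1L)
    }
})

test_that("pangenome inference partitions the genes and is deterministic
           given the seed", {
    sim <- cachedSim()
    gl <- pancore:::allGenes(sim$proteomes)
    pg1 <- inferPangenome(sim$proteomes, PanParams(rngSeed = 5))
    pg2 <- inferPangenome(sim$proteomes, PanParams(rngSeed = 5))
    expect_identical(panTable(pg1), panTable(pg2))
    expect_setequal(geneIds(pg1), names(gl$seqs))
    expect_false(anyDuplicated(geneIds(pg1)) > 0)
})

test_that("mutually dissimilar genes of one genome become singleton
           orthogroups", {
    seqs <- setNames(vapply(1:6, function(i) randomAa(50, 700 + i),
                            character(1)), paste0("g", 1:6))
    p <- makeProteome("solo", seqs)
    pg <- inferPangenome(list(p))
    expect_equal(length(orthogroupIds(pg)), 6L)
})

test_that("programmed in-paralogs are split into the two paralog groups
           by co-occurrence", {
    # 6 genomes, one family, every genome holds the original and a copy
    # diverged by ~30%
    base <- randomAa(80, 810)
    copyBase <- mutateAa(base, 0.3, 811)
    genomes <- sprintf("G%d", 1:6)
    proteomes <- lapply(genomes, function(g) {
        aa <- c(mutateAa(base, 0.03, 820 + match(g, genomes)),
                mutateAa(copyBase, 0.03, 830 + match(g, genomes)))
        names(aa) <- paste0(g, c("_p1", "_p2"))
        makeProteome(g, aa)
    })
    pg <- inferPangenome(proteomes)
    tb <- panTable(pg)
    expect_length(unique(tb$orthogroup), 2L)
    og1 <- tb$orthogroup[grepl("_p1", tb$gene)]
    og2 <- tb$orthogroup[grepl("_p2", tb$gene)]
    expect_length(unique(og1), 1L)
    expect_length(unique(og2), 1L)
    expect_false(og1[1] == og2[1])
})

test_that("superclustering bridges preclusters of one family via
           profiles", {
    # two tight subfamilies of one family, diverged ~25% from each other:
    # past the preclustering radius, within profile sensitivity
    base <- randomAa(150, 900)
    far <- mutateAa(base, 0.25, 901)
    seqs <- c(
        setNames(vapply(1:4, function(i) mutateAa(base, 0.02, 910 + i),
                        character(1)), paste0("a", 1:4)),
        setNames(vapply(1:4, function(i) mutateAa(far, 0.02, 920 + i),
                        character(1)), paste0("b", 1:4)))
    proteomes <- lapply(1:4, function(i) {
        aa <- seqs[c(i, 4 + i)]
        makeProteome(paste0("G", i), aa)
    })
    pcs <- precluster(pancore:::allGenes(proteomes)$seqs)
    expect_gt(length(pcs), 1L)   # preclustering alone fragments
    sc <- supercluster(proteomes, PanParams())
    expect_length(sc$clusters, 1L)
})
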