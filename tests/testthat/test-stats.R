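# Pangenome statistics: prevalence/completeness model, fixation
# frequencies, gene-pair metrics against brute-force enumeration, and
# phylogenetic sampling-order diagnostics.

# brute-force gene-pair precision/recall over explicit pair enumeration
oraclePrf <- function(pred, truth) {
    genes <- sort(geneIds(truth))
    predOf <- setNames(panTable(pred)$orthogroup, panTable(pred)$gene)
    truthOf <- setNames(panTable(truth)$orthogroup, panTable(truth)$gene)
    pairs <- combn(genes, 2)
    coP <- predOf[pairs[1, ]] == predOf[pairs[2, ]]
    coT <- truthOf[pairs[1, ]] == truthOf[pairs[2, ]]
    tp <- sum(coP & coT)
    prec <- if (sum(coP) == 0) 1 else tp / sum(coP)
    rec <- if (sum(coT) == 0) 1 else tp / sum(coT)
    c(precision = prec, recall = rec,
      F = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
}

test_that("a saturated presence matrix fits prevalence and completeness
           of 1", {
    m <- matrix(1, 10, 8)
    fit <- fitPrevalenceCompleteness(m)
    expect_equal(unname(prevalence(fit)), rep(1, 8), tolerance = 1e-4)
    expect_equal(unname(completeness(fit)), rep(1, 10), tolerance = 1e-4)
})

test_that("the log-likelihood never decreases across sweeps and known
           parameters are recovered", {
    withr::with_seed(550, {
        n <- 120; m <- 150
        q <- runif(m, 0.2, 1)
        cc <- runif(n, 0.8, 1)
        cc[1] <- 1
        P <- outer(cc, q)
        O <- matrix(rbinom(n * m, 1, P), n, m)
    })
    fit <- fitPrevalenceCompleteness(O)
    expect_true(all(diff(logLikTrace(fit)) >= -1e-8))
    expect_lt(mean(abs(prevalence(fit) - q)), 0.05)
    expect_s4_class(fit, "PrevalenceModel")
    expect_equal(max(completeness(fit)), 1)
})

test_that("a family present in every complete genome gets prevalence 1", {
    withr::with_seed(551, {
        O <- matrix(rbinom(200, 1, 0.5), 20, 10)
        O[, 1] <- 1
    })
    fit <- fitPrevalenceCompleteness(O)
    expect_gte(prevalence(fit)[1], 0.99)
})

test_that("all-zero rows or columns are flagged and clamped", {
    withr::with_seed(552, O <- matrix(rbinom(40, 1, 0.7), 8, 5))
    O[, 3] <- 0
    expect_warning(fit <- fitPrevalenceCompleteness(O), "all-zero")
    expect_lte(prevalence(fit)[3], 1e-5)
})

test_that("fixation frequency is the core-species fraction among
           present-species, with exact boundary values", {
    # 10 species x 4 genomes; FX core (all genomes) in 3 species,
    # sporadic (1 genome) in 7 species; FU core wherever present;
    # FZ never core; FBG universal backbone so every species fits
    species <- sprintf("S%02d", 1:10)
    rows <- list()
    for (s in seq_along(species)) {
        genomes <- sprintf("%s_g%d", species[s], 1:4)
        for (g in genomes) {
            rows[[length(rows) + 1]] <- data.frame(
                gene = paste0(g, "_bg"), genome = g, orthogroup = "FBG")
            rows[[length(rows) + 1]] <- data.frame(
                gene = paste0(g, "_bg2"), genome = g, orthogroup = "FBG2")
        }
        gset <- if (s <= 3) genomes else genomes[1]
        for (g in gset)
            rows[[length(rows) + 1]] <- data.frame(
                gene = paste0(g, "_fx"), genome = g, orthogroup = "FX")
        if (s <= 5)
            for (g in genomes)
                rows[[length(rows) + 1]] <- data.frame(
                    gene = paste0(g, "_fu"), genome = g,
                    orthogroup = "FU")
        rows[[length(rows) + 1]] <- data.frame(
            gene = paste0(genomes[2], "_fz"), genome = genomes[2],
            orthogroup = "FZ")
    }
    pg <- Pangenome(do.call(rbind, rows))
    spMap <- setNames(rep(species, each = 4),
                      unlist(lapply(species, function(s)
                          sprintf("%s_g%d", s, 1:4))))
    ff <- fixationFrequencies(pg, spMap, minGenomes = 4, minSpecies = 1,
                              corePrev = 0.95)
    get <- function(og) ff$fixationFreq[ff$orthogroup == og]
    expect_equal(get("FX"), 3 / 10)       # core in 3 of 10 present
    expect_equal(get("FU"), 1.0)          # core wherever present
    expect_equal(get("FZ"), 0.0)          # never core
    expect_equal(ff$nSpeciesPresent[ff$orthogroup == "FX"], 10L)
    # invariants
    expect_true(all(ff$fixationFreq >= 0 & ff$fixationFreq <= 1))
    expect_true(all((ff$fixationFreq == 1) ==
                    (ff$nSpeciesCore == ff$nSpeciesPresent)))
})

test_that("the minSpecies filter drops rare orthogroups", {
    species <- sprintf("S%02d", 1:4)
    rows <- do.call(rbind, lapply(species, function(s) {
        genomes <- sprintf("%s_g%d", s, 1:3)
        do.call(rbind, lapply(genomes, function(g)
            data.frame(gene = paste0(g, c("_a", "_b")), genome = g,
                       orthogroup = c("FA", "FB"))))
    }))
    rare <- data.frame(gene = "S01_g1_r", genome = "S01_g1",
                       orthogroup = "FR")
    pg <- Pangenome(rbind(rows, rare))
    spMap <- setNames(rep(species, each = 3),
                      unlist(lapply(species, function(s)
                          sprintf("%s_g%d", s, 1:3))))
    ff <- fixationFrequencies(pg, spMap, minGenomes = 3, minSpecies = 2)
    expect_false("FR" %in% ff$orthogroup)
    expect_true(all(c("FA", "FB") %in% ff$orthogroup))
})

test_that("gene-pair metrics match hand-computed and enumerated values", {
    truth <- Pangenome(paste0("g", 1:4), rep("G", 4), rep("F1", 4))
    pred <- Pangenome(paste0("g", 1:4), rep("G", 4),
                      c("A", "A", "B", "B"))
    prf <- genePairPrf(pred, truth)
    expect_equal(unname(prf), c(1, 1 / 3, 0.5))
    same <- genePairPrf(truth, truth)
    expect_equal(unname(same), c(1, 1, 1))
})

test_that("all-singleton predictions trigger the empty-pair convention", {
    truth <- Pangenome(paste0("g", 1:3), rep("G", 3), rep("F1", 3))
    pred <- Pangenome(paste0("g", 1:3), rep("G", 3), c("A", "B", "C"))
    expect_warning(prf <- genePairPrf(pred, truth), "precision")
    expect_equal(unname(prf["precision"]), 1)
    expect_equal(unname(prf["recall"]), 0)
})

test_that("gene-pair metrics equal brute-force enumeration on random
           partitions", {
    for (rep in 1:5) {
        withr::with_seed(660 + rep, {
            n <- sample(20:120, 1)
            genes <- sprintf("g%03d", 1:n)
            truth <- Pangenome(genes, rep("G", n),
                               sample(sprintf("T%d", 1:8), n, TRUE))
            pred <- Pangenome(genes, rep("G", n),
                              sample(sprintf("P%d", 1:6), n, TRUE))
        })
        expect_equal(genePairPrf(pred, truth), oraclePrf(pred, truth))
    }
})

test_that("differing gene universes are rejected with the symmetric
           difference size", {
    a <- Pangenome(c("g1", "g2"), c("G", "G"), c("F", "F"))
    b <- Pangenome(c("g1", "g3"), c("G", "G"), c("F", "F"))
    expect_error(genePairPrf(a, b), "2 genes")
})

test_that("identical pangenomes map 1:1 and disjoint ones not at all", {
    sim <- cachedSim()
    m <- mapOrthogroups(sim$truth, sim$truth)
    expect_equal(nrow(m), length(orthogroupIds(sim$truth)))
    expect_identical(m$a, m$b)
    prf <- coreConsistency(sim$truth, sim$truth)
    expect_equal(unname(prf[c("precision", "recall", "F")]), c(1, 1, 1))
    # disjoint gene ids share nothing
    other <- Pangenome(paste0("x", 1:5), rep("G", 5), rep("F9", 5))
    expect_equal(nrow(mapOrthogroups(sim$truth, other)), 0L)
})

test_that("ancestor discoveries follow node depths on a balanced tree", {
    tree <- ape::read.tree(text = paste0(
        "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,",
        "((t5:1,t6:1):1,(t7:1,t8:1):1):1);"))
    # root-to-tip order: each new tip discovers progressively younger
    # ancestors
    expect_equal(ancestorDiscoveryOrder(tree,
        c("t1", "t5", "t3", "t7", "t2", "t4", "t6", "t8")), 1)
    # k = 2: single discovery, 1 by convention
    expect_equal(ancestorDiscoveryOrder(tree, c("t1", "t2")), 1)
    # sampling close relatives first discovers young ancestors before the
    # root: strictly below 1
    frac <- ancestorDiscoveryOrder(tree, c("t1", "t2", "t3", "t5"))
    expect_lt(frac, 1)
    # brute-force check of that order: discoveries are MRCA(t2,t1) at
    # depth 2, MRCA(t3, closest of {t1,t2}) at depth 1,
    # MRCA(t5, ...) at depth 0 -> fractions of ordered pairs = 2/3... but
    # depth sequence 2,1,0 is strictly decreasing, so ordered fraction 0
    expect_equal(frac, 0)
    expect_error(ancestorDiscoveryOrder(tree, c("t1", "nope")), "nope")
})
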