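# Pangenome statistics and evaluation: joint prevalence/completeness
# estimation, gene fixation frequency, gene-pair precision/recall,
# orthogroup mapping between pangenomes, and phylogenetic sampling-order
# diagnostics.

#' Joint maximum-likelihood estimation of orthogroup prevalence and genome
#' completeness
#'
#' Models the binary presence of orthogroup j in genome i as Bernoulli with
#' success probability `c_i * q_j`, where `q_j` is the orthogroup's
#' prevalence and `c_i` the genome's completeness. Fitted by alternating
#' 1-D Newton updates (with backtracking, so the log-likelihood never
#' decreases) on each parameter block with the other fixed, parameters
#' clamped to `[eps, 1]`. After each sweep the completeness vector is
#' anchored at `max(c) = 1` (rescaling `q` accordingly), which fixes the
#' multiplicative non-identifiability of the model.
#'
#' @param presence genomes x orthogroups binary matrix (logical or 0/1),
#'   at least 2 x 2.
#' @param tol stop when the log-likelihood gain of a sweep drops below
#'   this (default 1e-6).
#' @param maxIter maximum sweeps.
#' @param eps lower clamp for parameters; all-zero rows/columns are set to
#'   `eps` with a warning.
#' @return a [PrevalenceModel-class].
#' @export
fitPrevalenceCompleteness <- function(presence, tol = 1e-6, maxIter = 200L,
                                      eps = 1e-6) {
    O <- matrix(as.numeric(presence), nrow = nrow(presence),
                dimnames = dimnames(presence))
    if (nrow(O) < 2L || ncol(O) < 2L)
        stop("presence matrix must be at least 2 genomes x 2 orthogroups")
    zRow <- rowSums(O) == 0
    zCol <- colSums(O) == 0
    if (any(zRow) || any(zCol))
        warning(sum(zRow), " all-zero genome(s) and ", sum(zCol),
                " all-zero orthogroup(s); their parameters are set to eps")
    q <- pmin(1 - eps, pmax(eps, colMeans(O)))
    cc <- rep(1 - eps, nrow(O))

    ll <- function(cc, q) {
        P <- pmin(1 - 1e-12, pmax(1e-12, outer(cc, q)))
        sum(O * log(P) + (1 - O) * log(1 - P))
    }
    newtonBlock <- function(par, other, byCol) {
        # update q (byCol) or c (!byCol) jointly with backtracking
        P <- if (byCol) outer(other, par) else outer(par, other)
        P <- pmin(1 - 1e-12, pmax(1e-12, P))
        Z <- (1 - O) / (1 - P)
        if (byCol) {
            n1 <- colSums(O)
            g <- n1 / par - colSums(Z * other)
            h <- -n1 / par^2 - colSums(Z^2 * other^2)
        } else {
            n1 <- rowSums(O)
            g <- n1 / par - rowSums(sweep(Z, 2, other, `*`))
            h <- -n1 / par^2 - rowSums(sweep(Z^2, 2, other^2, `*`))
        }
        step <- ifelse(is.finite(g / h), -g / h, 0)
        pmin(1, pmax(eps, par + step))
    }
    logLik <- ll(cc, q)
    for (it in seq_len(maxIter)) {
        prev <- logLik[length(logLik)]
        # q block with backtracking
        qNew <- newtonBlock(q, cc, byCol = TRUE)
        for (bt in 1:30) {
            if (ll(cc, qNew) >= prev - 1e-12) break
            qNew <- q + (qNew - q) / 2
        }
        if (ll(cc, qNew) >= prev - 1e-12) q <- qNew
        mid <- ll(cc, q)
        cNew <- newtonBlock(cc, q, byCol = FALSE)
        for (bt in 1:30) {
            if (ll(cNew, q) >= mid - 1e-12) break
            cNew <- cc + (cNew - cc) / 2
        }
        if (ll(cNew, q) >= mid - 1e-12) cc <- cNew
        # anchor max completeness at 1 (likelihood-invariant rescale)
        s <- max(cc)
        cc <- cc / s
        q <- pmin(1, pmax(eps, q * s))
        cur <- ll(cc, q)
        logLik <- c(logLik, cur)
        if (cur - prev < tol) break
    }
    q[zCol] <- eps
    cc[zRow] <- eps
    cc[which.max(cc)] <- 1
    new("PrevalenceModel", q = setNames(q, colnames(O)),
        c = setNames(cc, rownames(O)), logLik = logLik)
}

#' @describeIn fitPrevalenceCompleteness fitted orthogroup prevalences
#' @param object a [PrevalenceModel-class].
#' @export
prevalence <- function(object) object@q

#' @describeIn fitPrevalenceCompleteness fitted genome completeness values
#' @export
completeness <- function(object) object@c

#' @describeIn fitPrevalenceCompleteness per-sweep log-likelihood trace
#' @export
logLikTrace <- function(object) object@logLik

#' Gene fixation frequencies across species
#'
#' The fixation frequency of an orthogroup is the proportion of species
#' where it belongs to the species-level core genome, among the species
#' where it is present at all (in at least one genome). Species-level core
#' membership is decided by fitting the prevalence/completeness model per
#' species and requiring fitted prevalence `q >= corePrev`. Only species
#' with at least `minGenomes` genomes are considered, and records are
#' returned only for orthogroups present in at least `minSpecies` of those
#' species.
#'
#' @param pangenome a [Pangenome-class].
#' @param speciesMap named character vector mapping genome id to species;
#'   must cover all genomes of the pangenome.
#' @param minGenomes minimum genomes per retained species (default 10).
#' @param minSpecies minimum species an orthogroup must be present in
#'   (default 10).
#' @param corePrev fitted-prevalence threshold for species-core membership
#'   (default 0.95).
#' @return data.frame with columns `orthogroup`, `nSpeciesPresent`,
#'   `nSpeciesCore`, `fixationFreq`.
#' @export
fixationFrequencies <- function(pangenome, speciesMap, minGenomes = 10L,
                                minSpecies = 10L, corePrev = 0.95) {
    tb <- panTable(pangenome)
    missing <- setdiff(unique(tb$genome), names(speciesMap))
    if (length(missing))
        stop("speciesMap lacks genomes: ", paste(head(missing, 3),
             collapse = ", "))
    tb$species <- unname(speciesMap[tb$genome])
    genomesPerSpecies <- tapply(tb$genome, tb$species,
                                function(g) length(unique(g)))
    keepSpecies <- names(genomesPerSpecies)[genomesPerSpecies >=
                                            minGenomes]
    tb <- tb[tb$species %in% keepSpecies, , drop = FALSE]
    if (nrow(tb) == 0L)
        return(data.frame(orthogroup = character(),
                          nSpeciesPresent = integer(),
                          nSpeciesCore = integer(),
                          fixationFreq = numeric()))
    presentIn <- lapply(split(tb, tb$species),
                        function(d) unique(d$orthogroup))
    coreIn <- lapply(split(tb, tb$species), function(d) {
        pres <- table(d$genome, d$orthogroup) > 0
        pres <- matrix(pres, nrow = nrow(pres), dimnames = dimnames(pres))
        if (nrow(pres) < 2L || ncol(pres) < 2L)
            return(colnames(pres)[colMeans(pres) >= corePrev])
        fit <- fitPrevalenceCompleteness(pres)
        names(prevalence(fit))[prevalence(fit) >= corePrev]
    })
    nPresent <- table(unlist(presentIn, use.names = FALSE))
    nCore <- table(factor(unlist(coreIn, use.names = FALSE),
                          levels = names(nPresent)))
    keep <- nPresent >= minSpecies
    out <- data.frame(orthogroup = names(nPresent)[keep],
                      nSpeciesPresent = as.integer(nPresent[keep]),
                      nSpeciesCore = as.integer(nCore[keep]))
    out$fixationFreq <- out$nSpeciesCore / out$nSpeciesPresent
    out[order(out$orthogroup), , drop = FALSE]
}

#' Gene-pair precision, recall and F-measure of a predicted pangenome
#'
#' Over all unordered gene pairs: a pair is a true positive when
#' co-clustered in both pangenomes, a false positive when co-clustered
#' only in the prediction, a false negative when co-clustered only in the
#' truth. Computed from family-size contingency counts without
#' materialising pairs. An empty set of predicted (or truth) pairs yields
#' precision (recall) 1 by convention, with a warning.
#'
#' @param predicted,truth [Pangenome-class] objects over the same genes.
#' @return named numeric vector `precision`, `recall`, `F`.
#' @export
genePairPrf <- function(predicted, truth) {
    gp <- geneIds(predicted)
    gt <- geneIds(truth)
    if (length(gp) != length(gt) || !setequal(gp, gt)) {
        nd <- length(setdiff(gp, gt)) + length(setdiff(gt, gp))
        stop("gene universes differ (symmetric difference of ", nd,
             " genes)")
    }
    tp_ <- panTable(predicted)
    tt <- panTable(truth)
    predOf <- setNames(tp_$orthogroup, tp_$gene)
    truthOf <- setNames(tt$orthogroup, tt$gene)[names(predOf)]
    pairKey <- paste(predOf, truthOf, sep = "\r")
    nBoth <- table(pairKey)
    tp <- sum(choose(as.numeric(nBoth), 2))
    predPairs <- sum(choose(as.numeric(table(predOf)), 2))
    truthPairs <- sum(choose(as.numeric(table(truthOf)), 2))
    if (predPairs == 0) {
        warning("no co-clustered pairs predicted; precision set to 1")
        precision <- 1
    } else precision <- tp / predPairs
    if (truthPairs == 0) {
        warning("no co-clustered pairs in truth; recall set to 1")
        recall <- 1
    } else recall <- tp / truthPairs
    f <- if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, F = f)
}

#' Map orthogroups between two pangenomes
#'
#' Two orthogroups (one from each pangenome) are considered the same when
#' they share at least one gene copy in at least `sharePrev` of the
#' genomes in which either occurs (the rule is applied symmetrically to
#' both orthogroups' genome sets). Candidate pairs are matched 1:1
#' greedily, ties broken by largest shared-gene count and then by
#' lexicographic id.
#'
#' @param pgA,pgB [Pangenome-class] objects; gene ids shared between them
#'   define "shared copies" (the universes may differ, e.g. a core subset
#'   against a full pangenome).
#' @param sharePrev minimum shared-genome fraction (default 0.95).
#' @return data.frame with columns `a`, `b`, `nSharedGenes`, `fracA`,
#'   `fracB`.
#' @export
mapOrthogroups <- function(pgA, pgB, sharePrev = 0.95) {
    ta <- panTable(pgA)
    tbb <- panTable(pgB)
    shared <- merge(ta, tbb, by = "gene", suffixes = c("A", "B"))
    empty <- data.frame(a = character(), b = character(),
                        nSharedGenes = integer(), fracA = numeric(),
                        fracB = numeric())
    if (nrow(shared) == 0L) return(empty)
    genomesA <- tapply(ta$genome, ta$orthogroup,
                       function(g) length(unique(g)))
    genomesB <- tapply(tbb$genome, tbb$orthogroup,
                       function(g) length(unique(g)))
    key <- paste(shared$orthogroupA, shared$orthogroupB, sep = "\r")
    sharedGenomes <- tapply(shared$genomeA, key,
                            function(g) length(unique(g)))
    nGenes <- table(key)[names(sharedGenomes)]
    parts <- strsplit(names(sharedGenomes), "\r", fixed = TRUE)
    cand <- data.frame(a = vapply(parts, `[`, character(1), 1),
                       b = vapply(parts, `[`, character(1), 2),
                       nSharedGenes = as.integer(nGenes),
                       sharedGenomes = as.integer(sharedGenomes))
    cand$fracA <- cand$sharedGenomes / as.numeric(genomesA[cand$a])
    cand$fracB <- cand$sharedGenomes / as.numeric(genomesB[cand$b])
    cand <- cand[cand$fracA >= sharePrev & cand$fracB >= sharePrev, ,
                 drop = FALSE]
    if (nrow(cand) == 0L) return(empty)
    cand <- cand[order(-cand$nSharedGenes, cand$a, cand$b), , drop = FALSE]
    usedA <- character(0)
    usedB <- character(0)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
        if (cand$a[i] %in% usedA || cand$b[i] %in% usedB) next
        keep[i] <- TRUE
        usedA <- c(usedA, cand$a[i])
        usedB <- c(usedB, cand$b[i])
    }
    out <- cand[keep, c("a", "b", "nSharedGenes", "fracA", "fracB")]
    rownames(out) <- NULL
    out
}

#' Precision/recall of one core genome against a reference
#'
#' Maps the orthogroups of `corePg` to those of `referencePg` with
#' [mapOrthogroups()] and reports precision (matched / core families),
#' recall (matched / reference families) and their harmonic mean.
#'
#' @param corePg,referencePg [Pangenome-class] objects.
#' @param sharePrev mapping threshold (default 0.95).
#' @return named numeric vector `precision`, `recall`, `F`, `nMatched`.
#' @export
coreConsistency <- function(corePg, referencePg, sharePrev = 0.95) {
    m <- mapOrthogroups(corePg, referencePg, sharePrev)
    nA <- length(orthogroupIds(corePg))
    nB <- length(orthogroupIds(referencePg))
    precision <- if (nA == 0) 1 else nrow(m) / nA
    recall <- if (nB == 0) 1 else nrow(m) / nB
    f <- if (precision + recall == 0) 0 else
        2 * precision * recall / (precision + recall)
    c(precision = precision, recall = recall, F = f, nMatched = nrow(m))
}

#' Phylogenetic age-ordering of ancestor discoveries in a sampling order
#'
#' Each genome sampled after the first implies the discovery of the most
#' recent common ancestor of that genome and the closest (patristic
#' distance) genome already sampled. A phylogenetically representative
#' sampling discovers old ancestors before recent ones; this returns the
#' fraction of consecutive discovery pairs in which the earlier-discovered
#' ancestor is at least as old (no deeper from the root) as the later one.
#' A single discovery (`k = 2`) returns 1 by convention.
#'
#' @param tree a rooted `phylo` tree whose tips include the sampled
#'   genomes.
#' @param sampleOrder character vector of sampled tip labels, in sampling
#'   order (at least 2).
#' @return fraction in \[0, 1\].
#' @export
ancestorDiscoveryOrder <- function(tree, sampleOrder) {
    missing <- setdiff(sampleOrder, tree$tip.label)
    if (length(missing))
        stop("tip(s) missing from tree: ", paste(head(missing, 3),
             collapse = ", "))
    if (length(sampleOrder) < 2L)
        stop("need at least 2 sampled genomes")
    pat <- ape::cophenetic.phylo(tree)
    depths <- ape::node.depth.edgelength(tree)
    disc <- numeric(length(sampleOrder) - 1L)
    for (i in 2:length(sampleOrder)) {
        newTip <- sampleOrder[i]
        prev <- sampleOrder[seq_len(i - 1L)]
        d <- pat[newTip, prev]
        closest <- prev[order(d, prev)][1]
        mrca <- ape::getMRCA(tree, c(newTip, closest))
        disc[i - 1L] <- depths[mrca]
    }
    if (length(disc) == 1L) return(1)
    mean(diff(disc) >= -1e-9)
}
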