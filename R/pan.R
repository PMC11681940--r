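# Pangenome inference: superclustering of all genes followed by iterative
# binary splitting of each supercluster into orthogroups under a genome
# co-occurrence null model.

#' Supercluster all genes of a set of proteomes
#'
#' Two consecutive clustering operations: greedy k-mer preclustering of all
#' amino-acid sequences, then a profile-based merging step for increased
#' sensitivity. An alignment profile and consensus is built per precluster;
#' profiles are compared all-versus-all (restricted to pairs whose consensi
#' share k-mers) and preclusters are connected when their symmetrised
#' profile score reaches `superclusterFrac` times the smaller profile
#' self-score. Superclusters are the connected components.
#'
#' @param proteomes list of [Proteome-class] objects.
#' @param params a [PanParams-class].
#' @return list with `clusters` (list of data.frames with columns `gene`,
#'   `genome`; a partition of all genes), `msas` (per-supercluster cached
#'   alignment, where available).
#' @export
supercluster <- function(proteomes, params = PanParams()) {
    gl <- allGenes(proteomes)
    seqs <- gl$seqs
    genomes <- gl$genomes
    pcs <- precluster(seqs, minIdentity = params@preclusterIdentity)

    # one profile per precluster (representatives only, if very large)
    msas <- vector("list", length(pcs))
    profiles <- vector("list", length(pcs))
    for (i in seq_along(pcs)) {
        ids <- sort(pcs[[i]])
        sub <- seqs[ids]
        if (length(ids) > params@maxAlign) {
            reps <- ficlinReps(sub, params@nReps, params@rngSeed)
            aln <- alignSeqs(sub[reps])
        } else {
            aln <- alignSeqs(sub)
            msas[[i]] <- aln
        }
        profiles[[i]] <- buildProfile(aln, orthogroupId = as.character(i))
    }

    # profile-based merging of preclusters
    parent <- seq_along(pcs)
    findRoot <- function(i) {
        while (parent[i] != i) {
            parent[i] <<- parent[parent[i]]
            i <- parent[i]
        }
        i
    }
    if (length(pcs) > 1L) {
        cons <- vapply(profiles, consensusSeq, character(1))
        cand <- kmerCandidatePairsCpp(cons, 5L, 0.02)
        if (length(cand$i)) {
            self <- vapply(profiles, profileSelfScore, numeric(1))
            for (t in seq_along(cand$i)) {
                i <- cand$i[t] + 1L
                j <- cand$j[t] + 1L
                if (findRoot(i) == findRoot(j)) next
                sc <- scoreProfileProfile(profiles[[i]], profiles[[j]])
                if (sc >= params@superclusterFrac * min(self[i], self[j]))
                    parent[findRoot(j)] <- findRoot(i)
            }
        }
    }
    comp <- vapply(seq_along(pcs), findRoot, integer(1))
    groups <- split(seq_along(pcs), comp)
    clusters <- vector("list", length(groups))
    outMsas <- vector("list", length(groups))
    for (g in seq_along(groups)) {
        idx <- groups[[g]]
        ids <- sort(unlist(pcs[idx], use.names = FALSE))
        clusters[[g]] <- data.frame(gene = ids,
                                    genome = unname(genomes[ids]))
        if (length(idx) == 1L && !is.null(msas[[idx]]))
            outMsas[[g]] <- msas[[idx]]
    }
    ord <- order(vapply(clusters, function(cl) cl$gene[1], character(1)))
    list(clusters = clusters[ord], msas = outMsas[ord])
}

# representative selection among sequences: maximin traversal with
# d = 1 - k-mer identity (C++ specialisation of ficlinSelect)
ficlinReps <- function(seqs, nReps, seed) {
    n <- length(seqs)
    pivot <- withSeed(seed, sample.int(n, 1L)) - 1L
    res <- ficlinKmerCpp(unname(seqs), names(seqs), 5L,
                         as.integer(min(nReps, n)), pivot, -1)
    names(seqs)[res$order + 1L]
}

#' Propose a binary split of a gene cluster
#'
#' Representatives (all members if fewer than `maxAlign`, else `nReps`
#' selected by maximin traversal over k-mer distance) are aligned; a
#' distance matrix over columns where neither row is gapped feeds
#' average-linkage hierarchical clustering, which is cut at the root into
#' the two top-level groups. Non-representatives are then assigned to the
#' side of their closest representative (k-mer identity). Both sides
#' always retain at least one representative, so both are non-empty.
#'
#' @param cluster data.frame with columns `gene`, `genome`.
#' @param seqs named character vector covering the cluster's genes.
#' @param params a [PanParams-class].
#' @param msa optional precomputed alignment of all cluster members.
#' @return list of two data.frames (`A`, `B`), and the alignment rows used
#'   (`msaA`, `msaB`) when the whole cluster was aligned.
#' @export
proposeSplit <- function(cluster, seqs, params = PanParams(), msa = NULL) {
    n <- nrow(cluster)
    if (n < 2L) stop("cannot split a cluster with fewer than 2 genes")
    ids <- cluster$gene
    sub <- seqs[ids]
    if (n > params@maxAlign) {
        reps <- ficlinReps(sub, params@nReps, params@rngSeed)
        aln <- alignSeqs(sub[reps])
        full <- FALSE
    } else {
        reps <- ids
        aln <- if (!is.null(msa)) msa[ids] else alignSeqs(sub)
        full <- TRUE
    }
    D <- msaDistanceCpp(as.character(aln))
    dimnames(D) <- list(reps, reps)
    hc <- hclust(as.dist(D), method = "average")
    grp <- cutree(hc, k = 2)
    sideA <- reps[grp == 1]
    sideB <- reps[grp == 2]
    if (!full) {
        others <- setdiff(ids, reps)
        if (length(others)) {
            repIdx <- match(reps, ids)
            nearest <- nearestRepCpp(unname(sub[others]),
                                     repIdx - 1L, ids, 5L) + 1L
            nearestRep <- reps[nearest]
            sideA <- c(sideA, others[nearestRep %in% sideA])
            sideB <- c(sideB, others[nearestRep %in% sideB])
        }
    }
    rownames(cluster) <- cluster$gene
    list(A = cluster[sort(sideA), , drop = FALSE],
         B = cluster[sort(sideB), , drop = FALSE],
         msaA = if (full) aln[sort(sideA)] else NULL,
         msaB = if (full) aln[sort(sideB)] else NULL)
}

#' Evaluate a proposed binary split under the co-occurrence null model
#'
#' The split of a parent cluster into subclusters A and B is accepted when
#' the two subclusters co-occur in the same genomes at least as often as
#' expected under a null model in which the division of the parent's genes
#' into groups of the observed sizes is random. For a genome holding `k`
#' parent genes, with `n = |A| + |B|`, the probability that a random
#' size-`|A|` subset misses all `k` genes is hypergeometric,
#' `choose(n - k, |A|) / choose(n, |A|)` (likewise for B), and the
#' expected number of co-occurring genomes is the sum over genomes of
#' `1 - P(no A) - P(no B)`. A boundary rule makes strictly single-copy
#' clusters (`expected == observed == 0`) reject the split, so that
#' single-copy families are emitted whole.
#'
#' @param subA,subB disjoint non-empty data.frames with columns `gene`,
#'   `genome`.
#' @return list with `observed` (genomes containing at least one gene of
#'   each side), `expected` (null-model expectation), and `accepted`.
#' @export
evaluateSplit <- function(subA, subB) {
    if (nrow(subA) == 0L || nrow(subB) == 0L)
        stop("both subclusters must be non-empty")
    if (length(intersect(subA$gene, subB$gene)))
        stop("subclusters overlap")
    a <- nrow(subA)
    b <- nrow(subB)
    n <- a + b
    kg <- table(c(subA$genome, subB$genome))
    pNoA <- exp(lchoose(n - kg, a) - lchoose(n, a))
    pNoA[n - kg < a] <- 0
    pNoB <- exp(lchoose(n - kg, b) - lchoose(n, b))
    pNoB[n - kg < b] <- 0
    expected <- sum(1 - pNoA - pNoB)
    observed <- length(intersect(unique(subA$genome), unique(subB$genome)))
    accepted <- observed >= expected && !(observed == 0L && expected <= 0)
    list(observed = observed, expected = expected, accepted = accepted)
}

#' Infer a pangenome
#'
#' Superclusters all genes, then recursively splits each supercluster:
#' a binary split is proposed ([proposeSplit()]) and kept when the genome
#' co-occurrence test ([evaluateSplit()]) accepts it, in which case both
#' subclusters are split further; otherwise the cluster is emitted as one
#' orthogroup. Orthogroup ids are zero-padded integers prefixed `F`. The
#' result is deterministic given `params@rngSeed` and partitions the input
#' genes.
#'
#' @param proteomes list of [Proteome-class] objects.
#' @param params a [PanParams-class].
#' @return a [Pangenome-class].
#' @examples
#' sim <- simulatePangenome(nGenomes = 4, nCoreFamilies = 5,
#'                          nAccessoryFamilies = 3, seed = 7)
#' pg <- inferPangenome(sim$proteomes)
#' pg
#' @export
inferPangenome <- function(proteomes, params = PanParams()) {
    gl <- allGenes(proteomes)
    sc <- supercluster(proteomes, params)
    ogs <- list()
    for (ci in seq_along(sc$clusters)) {
        stack <- list(list(cl = sc$clusters[[ci]], msa = sc$msas[[ci]]))
        while (length(stack)) {
            node <- stack[[length(stack)]]
            stack[[length(stack)]] <- NULL
            cl <- node$cl
            if (nrow(cl) == 1L) {
                ogs[[length(ogs) + 1L]] <- cl
                next
            }
            sp <- proposeSplit(cl, gl$seqs, params, msa = node$msa)
            verdict <- evaluateSplit(sp$A, sp$B)
            if (verdict$accepted) {
                stack[[length(stack) + 1L]] <- list(cl = sp$B, msa = sp$msaB)
                stack[[length(stack) + 1L]] <- list(cl = sp$A, msa = sp$msaA)
            } else {
                ogs[[length(ogs) + 1L]] <- cl
            }
        }
    }
    fmt <- paste0("F%0", max(6L, nchar(length(ogs))), "d")
    rows <- do.call(rbind, lapply(seq_along(ogs), function(i) {
        cbind(ogs[[i]], orthogroup = sprintf(fmt, i))
    }))
    Pangenome(rows$gene, rows$genome, rows$orthogroup)
}
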