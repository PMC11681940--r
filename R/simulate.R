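# Synthetic pangenome generator with known orthogroup truth: a gene-family
# complement evolving by gain and loss along a random coalescent tree, with
# Jukes-Cantor point substitutions scaled to a target tip-tip nucleotide
# identity, and optional in-paralog duplications.

STOP_CODONS <- list(c(4L, 1L, 1L), c(4L, 1L, 3L), c(4L, 3L, 1L)) # TAA TAG TGA

isStopCodon <- function(codon) {
    (codon[1] == 4L && codon[2] == 1L && (codon[3] == 1L || codon[3] == 3L)) ||
        (codon[1] == 4L && codon[2] == 3L && codon[3] == 1L)
}

# random codon-multiple coding sequence without stop codons (integer-coded
# bases 1..4 = ACGT)
randomCodingSeq <- function(nCodons) {
    m <- matrix(sample.int(4L, 3L * nCodons, replace = TRUE), nrow = 3L)
    repeat {
        bad <- which(m[1, ] == 4L &
                     ((m[2, ] == 1L & (m[3, ] == 1L | m[3, ] == 3L)) |
                      (m[2, ] == 3L & m[3, ] == 1L)))
        if (length(bad) == 0L) break
        m[, bad] <- sample.int(4L, 3L * length(bad), replace = TRUE)
    }
    as.vector(m)
}

# apply nMut random point substitutions avoiding in-frame stop codons
mutateSeq <- function(seq, nMut) {
    if (nMut == 0L) return(seq)
    L <- length(seq)
    pos <- sample.int(L, nMut, replace = TRUE)
    shift <- sample.int(3L, nMut, replace = TRUE)
    for (t in seq_len(nMut)) {
        p <- pos[t]
        cur <- seq[p]
        cs <- p - (p - 1L) %% 3L
        placed <- FALSE
        for (dr in 0:2) {
            nb <- (cur - 1L + ((shift[t] - 1L + dr) %% 3L) + 1L) %% 4L + 1L
            codon <- seq[cs:(cs + 2L)]
            codon[p - cs + 1L] <- nb
            if (!isStopCodon(codon)) {
                seq[p] <- nb
                placed <- TRUE
                break
            }
        }
        # a substitution that can only create a stop is skipped
    }
    seq
}

#' Simulate a multi-genome dataset with known orthogroup truth
#'
#' Genomes evolve along a random coalescent tree. Core families are present
#' at the root and inherited by every tip; accessory families are gained on
#' a random branch (probability proportional to branch length) and can
#' subsequently be lost (a Poisson number of loss events per branch in
#' their subtree). Sequences are random stop-free coding sequences evolving
#' by Jukes-Cantor point substitutions, with branch lengths rescaled so
#' that the expected tip-to-tip nucleotide identity matches
#' `targetIdentity`. With probability `dupProb` a family acquires an
#' in-paralog copy on a random branch; the copy receives an extra
#' divergence burst (10% of sites) and then evolves along the subtree like
#' any other lineage. All randomness is governed by `seed`; the same seed
#' reproduces the dataset exactly.
#'
#' @param nGenomes number of genomes (tips).
#' @param nCoreFamilies families present at the root and never lost.
#' @param nAccessoryFamilies families gained along the tree.
#' @param targetIdentity expected tip-tip nucleotide identity (e.g. 0.90
#'   for a genus-level dataset, values near 1 for within-species data).
#' @param lossRate expected loss events per branch for accessory families.
#' @param dupProb per-family probability of an in-paralog duplication.
#' @param minLen,maxLen coding-sequence length range (nt; rounded to
#'   codons).
#' @param seed RNG seed.
#' @return list with `proteomes` (named list of [Proteome-class] with
#'   amino-acid and nucleotide sequences), `truth` (a [Pangenome-class]),
#'   `tree` (the scaled `phylo`), and `events` (data.frame of gain, loss
#'   and duplication events).
#' @export
simulatePangenome <- function(nGenomes = 100L, nCoreFamilies = 1000L,
                              nAccessoryFamilies = 2000L,
                              targetIdentity = 0.90, lossRate = 0.2,
                              dupProb = 0.02, minLen = 300L, maxLen = 1500L,
                              seed = 1L) {
    stopifnot(nGenomes >= 2L, targetIdentity > 0.25, targetIdentity <= 1,
              lossRate >= 0, dupProb >= 0, dupProb <= 1)
    withSeed(seed, {
        tree <- ape::rcoal(nGenomes,
                           tip.label = sprintf("genome%03d",
                                               seq_len(nGenomes)))
        # rescale branch lengths so the mean expected tip-tip Jukes-Cantor
        # identity equals targetIdentity
        D <- ape::cophenetic.phylo(tree)[upper.tri(diag(nGenomes))]
        s <- if (targetIdentity >= 1) 0 else
            stats::uniroot(function(s)
                mean(0.25 + 0.75 * exp(-4 / 3 * s * D)) - targetIdentity,
                c(1e-9, 1e4))$root
        tree$edge.length <- tree$edge.length * s
        tree <- stats::reorder(tree, "cladewise")  # parent before child
        edges <- tree$edge
        elen <- tree$edge.length
        nNodes <- max(edges)
        root <- nGenomes + 1L

        famIds <- c(sprintf("C%05d", seq_len(nCoreFamilies)),
                    sprintf("A%05d", seq_len(nAccessoryFamilies)))
        isCore <- c(rep(TRUE, nCoreFamilies), rep(FALSE, nAccessoryFamilies))
        # gain node per family: root for core, child of a random branch
        # (weighted by length) for accessory
        gainEdge <- sample.int(nrow(edges), nCoreFamilies +
                               nAccessoryFamilies, replace = TRUE,
                               prob = pmax(elen, 1e-12))
        gainNode <- ifelse(isCore, root, edges[gainEdge, 2])
        nCodons <- floor(sample(seq(minLen, maxLen), length(famIds),
                                replace = TRUE) / 3L)

        rawMap <- charToRaw("ACGT")
        genes <- list()        # per genome: named character nt sequences
        for (g in tree$tip.label) genes[[g]] <- list()
        events <- list()
        evAdd <- function(type, fam, node)
            events[[length(events) + 1L]] <<- data.frame(
                family = fam, type = type, node = node)

        for (f in seq_along(famIds)) {
            fam <- famIds[f]
            L <- 3L * nCodons[f]
            g0 <- gainNode[f]
            if (!isCore[f]) evAdd("gain", fam, g0)
            lossEdges <- integer(0)
            dupEdge <- 0L
            if (!isCore[f]) {
                # edges strictly below the gain node
                inSub <- descendantEdges(edges, g0)
                nLoss <- rpois(length(inSub), lossRate) > 0L
                lossEdges <- inSub[nLoss]
            }
            if (dupProb > 0 && runif(1) < dupProb) {
                cand <- if (isCore[f]) seq_len(nrow(edges)) else
                    descendantEdges(edges, g0)
                if (length(cand))
                    dupEdge <- cand[sample.int(length(cand), 1L)]
            }
            # evolve down the tree
            seqs <- vector("list", nNodes)       # primary copy
            dupSeqs <- vector("list", nNodes)    # duplicate copy
            seqs[[g0]] <- randomCodingSeq(nCodons[f])
            if (g0 <= nGenomes) {
                tip <- tree$tip.label[g0]
                genes[[tip]][[paste0(tip, "_", fam)]] <- seqs[[g0]]
            }
            for (e in seq_len(nrow(edges))) {
                par <- edges[e, 1]
                chd <- edges[e, 2]
                if (!is.null(seqs[[par]]) && !(e %in% lossEdges)) {
                    s <- mutateSeq(seqs[[par]], rpois(1L, L * elen[e]))
                    seqs[[chd]] <- s
                    if (e == dupEdge) {
                        evAdd("duplication", fam, chd)
                        dupSeqs[[chd]] <- mutateSeq(s, rpois(1L, 0.1 * L))
                    }
                } else if (e %in% lossEdges && !is.null(seqs[[par]])) {
                    evAdd("loss", fam, chd)
                }
                if (!is.null(dupSeqs[[par]]) && !(e %in% lossEdges))
                    dupSeqs[[chd]] <- mutateSeq(dupSeqs[[par]],
                                                rpois(1L, L * elen[e]))
                if (chd <= nGenomes) {
                    tip <- tree$tip.label[chd]
                    if (!is.null(seqs[[chd]]))
                        genes[[tip]][[paste0(tip, "_", fam)]] <- seqs[[chd]]
                    if (!is.null(dupSeqs[[chd]]))
                        genes[[tip]][[paste0(tip, "_", fam, "_b")]] <-
                            dupSeqs[[chd]]
                }
            }
        }

        emptyGenomes <- names(genes)[lengths(genes) == 0L]
        if (length(emptyGenomes))
            stop("configuration produced genome(s) without genes: ",
                 paste(head(emptyGenomes, 3), collapse = ", "))

        proteomes <- lapply(names(genes), function(g) {
            ntChar <- vapply(genes[[g]], function(s)
                rawToChar(rawMap[s]), character(1))
            nt <- Biostrings::DNAStringSet(ntChar)
            aa <- Biostrings::translate(nt, no.init.codon = TRUE)
            new("Proteome", genomeId = g, aa = aa, nt = nt)
        })
        names(proteomes) <- names(genes)

        rows <- do.call(rbind, lapply(names(genes), function(g) {
            ids <- names(genes[[g]])
            fams <- sub("_b$", "", sub("^[^_]*_", "", ids))
            data.frame(gene = ids, genome = g, orthogroup = fams)
        }))
        events <- if (length(events)) do.call(rbind, events) else
            data.frame(family = character(), type = character(),
                       node = integer())
        list(proteomes = proteomes,
             truth = Pangenome(rows$gene, rows$genome, rows$orthogroup),
             tree = tree, events = events)
    })
}

# indices of edges whose parent node lies in the clade rooted at `node`
descendantEdges <- function(edges, node) {
    inClade <- rep(FALSE, max(edges))
    inClade[node] <- TRUE
    out <- integer(0)
    for (e in seq_len(nrow(edges))) {   # edges are in preorder
        if (inClade[edges[e, 1]]) {
            inClade[edges[e, 2]] <- TRUE
            out <- c(out, e)
        }
    }
    out
}

#' Write a simulated dataset to disk
#'
#' Writes `faa/` and `ffn/` FASTA directories, the truth table as a
#' pangenome TSV, the tree as newick, and the event log as TSV.
#'
#' @param sim result of [simulatePangenome()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
    dir.create(file.path(dir, "faa"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(dir, "ffn"), recursive = TRUE, showWarnings = FALSE)
    for (g in names(sim$proteomes))
        writeProteome(sim$proteomes[[g]],
                      file.path(dir, "faa", paste0(g, ".faa")),
                      file.path(dir, "ffn", paste0(g, ".ffn")))
    writePangenome(sim$truth, file.path(dir, "truth.tsv"))
    ape::write.tree(sim$tree, file.path(dir, "tree.nwk"))
    atomicWrite(file.path(dir, "events.tsv"), function(tmp)
        write.table(sim$events, tmp, sep = "\t", quote = FALSE,
                    row.names = FALSE))
    invisible(dir)
}
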