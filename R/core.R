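# Direct core genome inference: pangenome of a random seed-genome subset,
# candidate core families, per-profile score cutoffs, genome-wide
# assignment through profile search.

#' Select random seed genomes
#'
#' Uniform sample without replacement of `n` genomes (all of them when
#' fewer are available), deterministic given `seed`.
#'
#' @param proteomes list of [Proteome-class] objects.
#' @param n number of seed genomes (default 100).
#' @param seed RNG seed.
#' @return character vector of genome ids, sorted.
#' @export
selectSeedGenomes <- function(proteomes, n = 100L, seed = 1L) {
    if (n < 1L) stop("n must be at least 1")
    ids <- names(asProteomeList(proteomes))
    if (length(ids) <= n) return(ids)
    sort(withSeed(seed, sample(ids, n)))
}

#' Candidate core orthogroups
#'
#' Orthogroups present in exactly one copy in at least `ceiling(prev * n)`
#' of the `n` genomes of the pangenome.
#'
#' @param pangenome a [Pangenome-class] (typically of the seed genomes).
#' @param prev minimum single-copy prevalence (default 0.90).
#' @return sorted character vector of orthogroup ids.
#' @export
candidateCore <- function(pangenome, prev = 0.90) {
    tb <- panTable(pangenome)
    if (nrow(tb) == 0L) return(character(0))
    nGenomes <- length(unique(tb$genome))
    need <- ceiling(prev * nGenomes)
    copies <- table(tb$orthogroup, tb$genome)
    singleCopy <- rowSums(copies == 1L)
    sort(names(singleCopy)[singleCopy >= need])
}

#' Calibrate a per-profile membership score cutoff
#'
#' The cutoff is the midpoint between the mean score of sequences belonging
#' to the family and the mean of the best non-member score per genome (the
#' discriminative boundary is against the closest paralogs). With no
#' non-member hits the cutoff falls back to half the member mean.
#'
#' @param profile a [Profile-class].
#' @param memberScores scores of sequences assigned to the family (at
#'   least one required).
#' @param nonmemberScores best non-member score per genome (possibly
#'   empty).
#' @return a [CoreProfile-class].
#' @export
calibrateCutoff <- function(profile, memberScores, nonmemberScores =
                                numeric(0)) {
    if (length(memberScores) == 0L)
        stop("cutoff calibration needs at least one member score")
    mm <- mean(memberScores)
    cutoff <- if (length(nonmemberScores) == 0L) 0.5 * mm
              else (mm + mean(nonmemberScores)) / 2
    new("CoreProfile", profile, cutoff = cutoff)
}

# build per-orthogroup MSAs and profiles for the given orthogroups
familyProfiles <- function(pangenome, seqs, orthogroups, params) {
    tb <- panTable(pangenome)
    msas <- list()
    profiles <- list()
    for (og in orthogroups) {
        ids <- sort(tb$gene[tb$orthogroup == og])
        if (length(ids) == 0L) stop("orthogroup '", og,
                                    "' absent from pangenome")
        sub <- seqs[ids]
        if (length(ids) > params@maxAlign)
            sub <- sub[ficlinReps(sub, params@nReps, params@rngSeed)]
        msas[[og]] <- alignSeqs(sub)
        profiles[[og]] <- buildProfile(msas[[og]], orthogroupId = og)
    }
    list(msas = msas, profiles = profiles)
}

# assign genes to the best-scoring profile whose cutoff they pass;
# hits: data.frame(gene, orthogroup, score); cutoffs named by orthogroup
assignByCutoff <- function(hits, cutoffs) {
    hits <- hits[hits$score >= cutoffs[hits$orthogroup], , drop = FALSE]
    if (nrow(hits) == 0L) return(hits)
    hits <- hits[order(hits$gene, -hits$score, hits$orthogroup), ,
                 drop = FALSE]
    hits[!duplicated(hits$gene), , drop = FALSE]
}

#' Infer the core genome directly
#'
#' Four steps: (1) infer the pangenome of a random subset of seed genomes;
#' (2) identify candidate core families (single copy in at least
#' `candidateCorePrev` of the seeds) and build an alignment profile per
#' family; (3) search the profiles against all seed sequences, calibrate a
#' per-profile score cutoff ([calibrateCutoff()]), re-assign seed
#' membership by cutoff, and keep families single-copy in at least
#' `finalCorePrev` of seeds; (4) search the profiles against the non-seed
#' genomes and assign genes passing the cutoffs. Each gene is assigned to
#' at most one (best-scoring) core family.
#'
#' @param proteomes list of [Proteome-class] objects (at least 2).
#' @param params a [PanParams-class].
#' @param maxCore optional cap: keep only the `maxCore` most prevalent
#'   final core families.
#' @return list with `core` (a [Pangenome-class] restricted to core
#'   orthogroups) and `db` (a [ProfileDB-class] with calibrated cutoffs).
#' @export
inferCore <- function(proteomes, params = PanParams(), maxCore = NULL) {
    proteomes <- asProteomeList(proteomes)
    if (length(proteomes) < 2L)
        stop("core inference needs at least 2 genomes")
    if (length(proteomes) < params@nSeedGenomes)
        warning("fewer genomes (", length(proteomes),
                ") than requested seeds (", params@nSeedGenomes,
                "); using all genomes as seeds")
    seeds <- selectSeedGenomes(proteomes, params@nSeedGenomes,
                               params@rngSeed)
    seedPg <- inferPangenome(proteomes[seeds], params)

    cand <- candidateCore(seedPg, params@candidateCorePrev)
    emptyOut <- list(core = Pangenome(character(0), character(0),
                                      character(0)),
                     db = new("ProfileDB", profiles = list(), msas = list()))
    if (length(cand) == 0L) return(emptyOut)

    gl <- allGenes(proteomes)
    seedGenes <- names(gl$genomes)[gl$genomes %in% seeds]
    fp <- familyProfiles(seedPg, gl$seqs, cand, params)

    # step 3: search against seed sequences, calibrate cutoffs
    hits <- searchProfiles(fp$profiles, gl$seqs[seedGenes])
    hits$genome <- unname(gl$genomes[hits$gene])
    tb <- panTable(seedPg)
    membership <- setNames(tb$orthogroup, tb$gene)
    cutoffs <- numeric(0)
    keepCand <- character(0)
    for (og in cand) {
        h <- hits[hits$orthogroup == og, , drop = FALSE]
        isMember <- !is.na(membership[h$gene]) & membership[h$gene] == og
        mem <- h$score[isMember]
        if (length(mem) == 0L) {
            warning("no member hits for candidate family ", og,
                    "; dropped")
            next
        }
        nonmem <- h[!isMember, , drop = FALSE]
        bestNon <- if (nrow(nonmem)) vapply(split(nonmem$score,
                                                  nonmem$genome),
                                            max, numeric(1)) else numeric(0)
        cp <- calibrateCutoff(fp$profiles[[og]], mem, bestNon)
        cutoffs[og] <- cp@cutoff
        keepCand <- c(keepCand, og)
    }
    if (length(keepCand) == 0L) return(emptyOut)

    seedAssign <- assignByCutoff(hits[hits$orthogroup %in% keepCand, ,
                                      drop = FALSE], cutoffs)
    need <- ceiling(params@finalCorePrev * length(seeds))
    copies <- table(factor(seedAssign$orthogroup, levels = keepCand),
                    seedAssign$genome)
    singleCopy <- rowSums(copies == 1L)
    final <- sort(names(singleCopy)[singleCopy >= need])
    if (length(final) == 0L) return(emptyOut)
    if (!is.null(maxCore) && length(final) > maxCore) {
        ord <- order(-singleCopy[final], final)
        final <- sort(final[ord][seq_len(maxCore)])
    }

    # step 4: assign non-seed genes
    nonSeedGenes <- names(gl$genomes)[!(gl$genomes %in% seeds)]
    rows <- seedAssign[seedAssign$orthogroup %in% final, , drop = FALSE]
    if (length(nonSeedGenes)) {
        nsHits <- searchProfiles(fp$profiles[final], gl$seqs[nonSeedGenes])
        nsAssign <- assignByCutoff(nsHits, cutoffs)
        nsAssign$genome <- unname(gl$genomes[nsAssign$gene])
        rows <- rbind(rows[c("gene", "genome", "orthogroup")],
                      nsAssign[c("gene", "genome", "orthogroup")])
    } else {
        rows <- rows[c("gene", "genome", "orthogroup")]
    }
    rows <- rows[order(rows$orthogroup, rows$genome, rows$gene), ,
                 drop = FALSE]
    db <- new("ProfileDB",
              profiles = setNames(lapply(final, function(og)
                  new("CoreProfile", fp$profiles[[og]],
                      cutoff = unname(cutoffs[og]))), final),
              msas = fp$msas[final])
    list(core = Pangenome(rows$gene, rows$genome, rows$orthogroup), db = db)
}
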