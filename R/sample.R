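# ANI between genomes from shared single-copy genes, optional trimmed mean
# (tcANI), and representative genome subsampling by farthest-first
# traversal over 1 - ANI.

# parse "mean" / "meanXX" into a per-tail trim fraction
aniTrimFraction <- function(method) {
    if (!grepl("^mean([0-9]{2})?$", method))
        stop("ANI method must be 'mean' or 'meanXX' (e.g. 'mean90')")
    if (method == "mean") return(0)
    (100 - as.numeric(sub("mean", "", method))) / 200
}

#' Average nucleotide (or amino-acid) identity between two genomes
#'
#' Per orthogroup with exactly one copy in each of the two genomes, the two
#' member sequences are globally aligned and their identity recorded;
#' the ANI is the mean of these per-gene identities. With a core-genome
#' pangenome this is the core-genome ANI (cANI). `method = "meanXX"`
#' gives the trimmed variant (tcANI): `floor(tail * m)` genes are dropped
#' from each tail of the sorted identities, with `tail = (100 - XX) / 200`
#' (so `mean90` keeps the middle 90%). Nucleotide sequences are used when
#' both genomes provide them; otherwise identity is computed on the
#' amino-acid level (an AAI rather than an ANI).
#'
#' @param pangenome a [Pangenome-class] covering both genomes.
#' @param proteomes list of [Proteome-class] objects.
#' @param genomeA,genomeB genome ids.
#' @param method `"mean"` or `"meanXX"`.
#' @return identity fraction in \[0, 1\]; `NA` (with a warning) when the
#'   genomes share no single-copy family. Attribute `nGenes` holds the
#'   number of genes averaged.
#' @export
pairwiseAni <- function(pangenome, proteomes, genomeA, genomeB,
                        method = "mean") {
    trim <- aniTrimFraction(method)
    proteomes <- asProteomeList(proteomes)
    tb <- panTable(pangenome)
    ta <- tb[tb$genome == genomeA, , drop = FALSE]
    tbB <- tb[tb$genome == genomeB, , drop = FALSE]
    ogA <- names(which(table(ta$orthogroup) == 1L))
    ogB <- names(which(table(tbB$orthogroup) == 1L))
    shared <- sort(intersect(ogA, ogB))
    if (length(shared) == 0L) {
        warning("no shared single-copy families between ", genomeA,
                " and ", genomeB)
        return(structure(NA_real_, nGenes = 0L))
    }
    gA <- setNames(ta$gene, ta$orthogroup)[shared]
    gB <- setNames(tbB$gene, tbB$orthogroup)[shared]
    pA <- proteomes[[genomeA]]
    pB <- proteomes[[genomeB]]
    useNt <- !is.null(pA@nt) && !is.null(pB@nt) &&
        all(gA %in% names(pA@nt)) && all(gB %in% names(pB@nt))
    idents <- vapply(seq_along(shared), function(i) {
        if (useNt)
            globalAlign(pA@nt[[gA[i]]], pB@nt[[gB[i]]], type = "nt")$identity
        else
            globalAlign(stripStop(as.character(pA@aa[[gA[i]]])),
                        stripStop(as.character(pB@aa[[gB[i]]])),
                        type = "aa")$identity
    }, numeric(1))
    m <- length(idents)
    drop <- floor(trim * m)
    if (drop > 0) {
        idents <- sort(idents)[(drop + 1):(m - drop)]
    }
    structure(mean(idents), nGenes = m)
}

#' Representative genome subsampling
#'
#' Farthest-first traversal ([ficlinSelect()]) over the genomes, with
#' distance `1 - ANI` (computed lazily and cached, so at most `k * n`
#' genome pairs are ever aligned). Sampling stops after `k` genomes or
#' before the first pick whose novelty would drop below
#' `1 - maxIdentity`. With `speciesMap`, sampling runs independently
#' within each species, honouring a per-species cap and the identity
#' ceiling.
#'
#' @param pangenome a core or full [Pangenome-class] covering the genomes.
#' @param proteomes list of [Proteome-class] objects.
#' @param k number of genomes to sample (defaults to all).
#' @param maxIdentity stop sampling once remaining genomes are all within
#'   this identity of the sample (e.g. 0.9999).
#' @param method ANI method, `"mean"` or `"meanXX"`.
#' @param seed RNG seed.
#' @param speciesMap optional named character vector mapping genome id to
#'   species.
#' @param perSpeciesCap cap on genomes sampled per species (with
#'   `speciesMap`).
#' @return a [SampleTrace-class]; with `speciesMap` the trace has an extra
#'   `species` column and per-species sampling order.
#' @export
sampleGenomes <- function(pangenome, proteomes, k = NULL,
                          maxIdentity = NULL, method = "mean", seed = 1L,
                          speciesMap = NULL, perSpeciesCap = NULL) {
    proteomes <- asProteomeList(proteomes)
    genomes <- sort(intersect(names(proteomes), genomeIds(pangenome)))
    if (length(genomes) == 0L) stop("pangenome covers none of the genomes")
    stopNovelty <- if (is.null(maxIdentity)) NULL else 1 - maxIdentity

    makeDist <- function() {
        cache <- new.env(parent = emptyenv())
        function(a, b) {
            if (a == b) return(0)
            key <- paste(sort(c(a, b)), collapse = "\r")
            if (!is.null(cache[[key]])) return(cache[[key]])
            ani <- suppressWarnings(
                pairwiseAni(pangenome, proteomes, a, b, method))
            d <- if (is.na(ani)) 1 else 1 - ani
            cache[[key]] <- d
            d
        }
    }

    if (is.null(speciesMap)) {
        kk <- if (is.null(k)) length(genomes) else min(k, length(genomes))
        return(ficlinSelect(genomes, makeDist(), k = kk,
                            stopNovelty = stopNovelty, seed = seed))
    }
    missing <- setdiff(genomes, names(speciesMap))
    if (length(missing))
        stop("speciesMap lacks genomes: ", paste(head(missing, 3),
             collapse = ", "))
    traces <- lapply(sort(unique(speciesMap[genomes])), function(sp) {
        g <- genomes[speciesMap[genomes] == sp]
        kk <- length(g)
        if (!is.null(perSpeciesCap)) kk <- min(kk, perSpeciesCap)
        if (!is.null(k)) kk <- min(kk, k)
        tr <- ficlinSelect(g, makeDist(), k = kk,
                           stopNovelty = stopNovelty, seed = seed)
        df <- sampleTrace(tr)
        df$species <- sp
        list(df = df, calls = nDistCalls(tr))
    })
    new("SampleTrace",
        trace = do.call(rbind, lapply(traces, `[[`, "df")),
        nDistCalls = sum(vapply(traces, `[[`, integer(1), "calls")))
}

#' Random subset of core orthogroups
#'
#' Uniform seeded sample of `nGenes` orthogroup ids (all when fewer
#' exist); used to compute ANI from a reduced core-gene set.
#'
#' @param pangenome a [Pangenome-class].
#' @param nGenes subset size (default 100).
#' @param seed RNG seed.
#' @return sorted character vector of orthogroup ids.
#' @export
subsetCore <- function(pangenome, nGenes = 100L, seed = 1L) {
    ogs <- orthogroupIds(pangenome)
    if (length(ogs) <= nGenes) return(ogs)
    sort(withSeed(seed, sample(ogs, nGenes)))
}

#' Restrict a pangenome to a set of orthogroups
#' @param pangenome a [Pangenome-class].
#' @param orthogroups orthogroup ids to keep.
#' @return a [Pangenome-class].
#' @export
subsetPangenome <- function(pangenome, orthogroups) {
    tb <- panTable(pangenome)
    Pangenome(tb[tb$orthogroup %in% orthogroups, , drop = FALSE])
}
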