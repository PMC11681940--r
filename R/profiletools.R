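# Profile database utilities: persist calibrated family profiles, identify
# family members in new genomes, and build a concatenated core-gene
# nucleotide supermatrix.

#' Build a profile database for chosen orthogroups
#'
#' Per orthogroup: a multiple sequence alignment of the member amino-acid
#' sequences, an alignment profile, and a membership score cutoff
#' calibrated as in core inference (midpoint between the member score mean
#' and the mean best non-member score per genome).
#'
#' @param pangenome a [Pangenome-class].
#' @param proteomes list of [Proteome-class] objects.
#' @param orthogroups orthogroup ids to include (default: all in the
#'   pangenome). An id absent from the pangenome is an error.
#' @param params a [PanParams-class].
#' @return a [ProfileDB-class].
#' @export
buildProfileDb <- function(pangenome, proteomes, orthogroups = NULL,
                           params = PanParams()) {
    gl <- allGenes(proteomes)
    if (is.null(orthogroups)) orthogroups <- orthogroupIds(pangenome)
    missing <- setdiff(orthogroups, orthogroupIds(pangenome))
    if (length(missing))
        stop("orthogroup '", missing[1], "' absent from pangenome")
    fp <- familyProfiles(pangenome, gl$seqs, orthogroups, params)
    hits <- searchProfiles(fp$profiles, gl$seqs)
    hits$genome <- unname(gl$genomes[hits$gene])
    tb <- panTable(pangenome)
    membership <- setNames(tb$orthogroup, tb$gene)
    profiles <- list()
    for (og in orthogroups) {
        h <- hits[hits$orthogroup == og, , drop = FALSE]
        isMember <- !is.na(membership[h$gene]) & membership[h$gene] == og
        mem <- h$score[isMember]
        if (length(mem) == 0L) {
            warning("no member hits for family ", og, "; dropped from DB")
            next
        }
        nonmem <- h[!isMember, , drop = FALSE]
        bestNon <- if (nrow(nonmem)) vapply(split(nonmem$score,
                                                  nonmem$genome),
                                            max, numeric(1)) else numeric(0)
        profiles[[og]] <- calibrateCutoff(fp$profiles[[og]], mem, bestNon)
    }
    new("ProfileDB", profiles = profiles,
        msas = fp$msas[names(profiles)])
}

#' Identify family members in proteomes with a profile database
#'
#' Each profile is searched against all sequences; hits at or above the
#' profile's cutoff are kept and each gene is assigned to its single
#' best-scoring passing profile.
#'
#' @param db a [ProfileDB-class].
#' @param proteomes list of [Proteome-class] objects.
#' @return a [Pangenome-class] with rows only for assigned genes.
#' @export
searchProfileDb <- function(db, proteomes) {
    if (length(db@profiles) == 0L) stop("empty profile database")
    gl <- allGenes(proteomes)
    hits <- searchProfiles(db@profiles, gl$seqs)
    cutoffs <- vapply(db@profiles, function(p) p@cutoff, numeric(1))
    assign <- assignByCutoff(hits, cutoffs)
    Pangenome(assign$gene, unname(gl$genomes[assign$gene]),
              assign$orthogroup)
}

#' Write / read a profile database directory
#'
#' Layout: `msa/<orthogroup>.aln` (aligned FASTA), `profiles.tsv`
#' (orthogroup, consensus, cutoff), and `freqs.tsv` (orthogroup, column,
#' kept, residue, frequency). `readProfileDb(writeProfileDb(db))`
#' reproduces consensi and cutoffs.
#'
#' @param db a [ProfileDB-class].
#' @param dir database directory.
#' @return `dir` (write) or a [ProfileDB-class] (read).
#' @export
writeProfileDb <- function(db, dir) {
    dir.create(file.path(dir, "msa"), recursive = TRUE, showWarnings = FALSE)
    for (og in names(db@msas))
        atomicWrite(file.path(dir, "msa", paste0(og, ".aln")),
                    function(tmp)
                        Biostrings::writeXStringSet(db@msas[[og]], tmp))
    prof <- data.frame(orthogroup = names(db@profiles),
                       consensus = vapply(db@profiles, consensusSeq,
                                          character(1)),
                       cutoff = vapply(db@profiles, function(p) p@cutoff,
                                       numeric(1)),
                       nSeqs = vapply(db@profiles, function(p) p@nSeqs,
                                      integer(1)))
    atomicWrite(file.path(dir, "profiles.tsv"), function(tmp)
        write.table(prof, tmp, sep = "\t", quote = FALSE,
                    row.names = FALSE))
    freqs <- do.call(rbind, lapply(names(db@profiles), function(og) {
        p <- db@profiles[[og]]
        L <- ncol(p@freq)
        data.frame(orthogroup = og,
                   column = rep(seq_len(L), each = 20L),
                   kept = rep(p@keep, each = 20L),
                   residue = rep(AA20, L),
                   freq = as.vector(p@freq))
    }))
    atomicWrite(file.path(dir, "freqs.tsv"), function(tmp)
        write.table(freqs, tmp, sep = "\t", quote = FALSE,
                    row.names = FALSE))
    invisible(dir)
}

#' @rdname writeProfileDb
#' @export
readProfileDb <- function(dir) {
    prof <- utils::read.delim(file.path(dir, "profiles.tsv"),
                              colClasses = c("character", "character",
                                             "numeric", "integer"))
    freqs <- utils::read.delim(file.path(dir, "freqs.tsv"))
    profiles <- list()
    msas <- list()
    for (i in seq_len(nrow(prof))) {
        og <- prof$orthogroup[i]
        f <- freqs[freqs$orthogroup == og, , drop = FALSE]
        L <- max(f$column)
        fm <- matrix(f$freq, nrow = 20L, dimnames = list(AA20, NULL))
        keep <- f$kept[match(seq_len(L), f$column)]
        profiles[[og]] <- new("CoreProfile",
            orthogroupId = og, freq = fm, keep = keep,
            consensus = prof$consensus[i], nSeqs = prof$nSeqs[i],
            cutoff = prof$cutoff[i])
        aln <- file.path(dir, "msa", paste0(og, ".aln"))
        msas[[og]] <- Biostrings::AAStringSet(toupper(as.character(
            Biostrings::readBStringSet(aln))))
        names(msas[[og]]) <- sub("\\s.*$", "",
            names(Biostrings::readBStringSet(aln)))
    }
    new("ProfileDB", profiles = profiles, msas = msas)
}

# nucleotide sequence of a gene with a trailing stop codon removed when the
# lengths allow it; NULL when nt/aa lengths disagree beyond one codon
codingSeq <- function(proteome, gene) {
    if (is.null(proteome@nt) || !(gene %in% names(proteome@nt)))
        return(NULL)
    nt <- as.character(proteome@nt[[gene]])
    aa <- stripStop(as.character(proteome@aa[[gene]]))
    expect <- 3L * nchar(aa)
    if (nchar(nt) == expect + 3L) nt <- substr(nt, 1L, expect)
    if (abs(nchar(nt) - expect) > 3L) return(NULL)
    if (nchar(nt) != expect) return(NULL)
    nt
}

#' Concatenated core-gene nucleotide supermatrix
#'
#' Per core family (in sorted orthogroup order): all copies are removed
#' from genomes holding more than one copy; the remaining member sequences
#' are aligned on the amino-acid level; the amino acids are then replaced
#' by their codons (gap columns become `---`); and the per-family blocks
#' are concatenated horizontally. Genomes missing a family get an all-gap
#' block. Genes whose nucleotide and amino-acid lengths disagree beyond
#' one codon are skipped with a warning.
#'
#' @param pangenome a [Pangenome-class] (typically core orthogroups only).
#' @param proteomes list of [Proteome-class] objects with nucleotide
#'   sequences.
#' @return a [Supermatrix-class] with one row per genome in the pangenome.
#' @export
concatSupermatrix <- function(pangenome, proteomes) {
    proteomes <- asProteomeList(proteomes)
    tb <- panTable(pangenome)
    genomes <- sort(unique(tb$genome))
    ogs <- sort(unique(tb$orthogroup))
    rows <- setNames(rep(list(character(0)), length(genomes)), genomes)
    blocks <- data.frame(orthogroup = character(), start = integer(),
                         end = integer())
    pos <- 0L
    for (og in ogs) {
        sub <- tb[tb$orthogroup == og, , drop = FALSE]
        multi <- names(which(table(sub$genome) > 1L))
        sub <- sub[!(sub$genome %in% multi), , drop = FALSE]
        nts <- character(0)
        aas <- character(0)
        keptGenomes <- character(0)
        for (i in seq_len(nrow(sub))) {
            g <- sub$genome[i]
            nt <- codingSeq(proteomes[[g]], sub$gene[i])
            if (is.null(nt)) {
                warning("gene ", sub$gene[i],
                        " skipped in concat (nt/aa length mismatch or ",
                        "missing nt)")
                next
            }
            nts <- c(nts, nt)
            aas <- c(aas, stripStop(as.character(
                proteomes[[g]]@aa[[sub$gene[i]]])))
            keptGenomes <- c(keptGenomes, g)
        }
        if (length(aas) == 0L) next
        names(aas) <- keptGenomes
        aln <- as.character(alignSeqs(aas))
        width <- nchar(aln[1])
        blockNt <- setNames(vapply(seq_along(aln), function(i)
            backTranslate(aln[i], nts[i]), character(1)), keptGenomes)
        gapBlock <- strrep("-", 3L * width)
        for (g in genomes)
            rows[[g]] <- c(rows[[g]],
                           if (g %in% keptGenomes) blockNt[[g]] else
                           gapBlock)
        blocks <- rbind(blocks, data.frame(orthogroup = og,
                                           start = pos + 1L,
                                           end = pos + 3L * width))
        pos <- pos + 3L * width
    }
    aln <- Biostrings::DNAStringSet(vapply(rows, paste, character(1),
                                           collapse = ""))
    names(aln) <- genomes
    new("Supermatrix", aln = aln, blockMap = blocks)
}

# replace each residue of an aligned amino-acid row by its codon, gaps by
# "---"
backTranslate <- function(alignedAa, nt) {
    chars <- strsplit(alignedAa, "", fixed = TRUE)[[1]]
    codons <- character(length(chars))
    j <- 0L
    for (i in seq_along(chars)) {
        if (chars[i] == "-") codons[i] <- "---"
        else {
            codons[i] <- substr(nt, 3L * j + 1L, 3L * j + 3L)
            j <- j + 1L
        }
    }
    paste(codons, collapse = "")
}

#' @describeIn concatSupermatrix write the supermatrix as aligned FASTA
#'   plus a block-map TSV
#' @param sm a [Supermatrix-class].
#' @param fastaPath,blockPath output paths.
#' @export
writeSupermatrix <- function(sm, fastaPath, blockPath = NULL) {
    atomicWrite(fastaPath, function(tmp)
        Biostrings::writeXStringSet(sm@aln, tmp))
    if (!is.null(blockPath))
        atomicWrite(blockPath, function(tmp)
            write.table(sm@blockMap, tmp, sep = "\t", quote = FALSE,
                        row.names = FALSE))
    invisible(fastaPath)
}
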