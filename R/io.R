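#' Read a proteome from a FASTA file
#'
#' Reads one genome's predicted genes from an amino-acid FASTA file. The
#' gene id is the header token before the first whitespace; sequences are
#' uppercased but otherwise kept byte-for-byte (including a trailing stop
#' `*` if present). The genome id defaults to the file name stem.
#'
#' @param path amino-acid FASTA file.
#' @param ntPath optional nucleotide FASTA with coding sequences for (a
#'   subset of) the same gene ids.
#' @param genomeId genome identifier; defaults to the file name without its
#'   extension.
#' @return a [Proteome-class].
#' @examples
#' faa <- tempfile(fileext = ".faa")
#' writeLines(c(">g1 desc", "MKV*", ">g2", "MAARW"), faa)
#' p <- readProteome(faa)
#' length(aaSeqs(p))
#' @export
readProteome <- function(path, ntPath = NULL, genomeId = NULL) {
    if (is.null(genomeId))
        genomeId <- sub("\\.[^.]*$", "", basename(path))
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) stop("no FASTA entries in ", path)
    ids <- sub("\\s.*$", "", names(raw))
    if (anyDuplicated(ids)) {
        d <- ids[duplicated(ids)][1]
        stop("duplicate gene id '", d, "' in ", path)
    }
    aa <- Biostrings::AAStringSet(toupper(as.character(raw)))
    names(aa) <- ids
    nt <- NULL
    if (!is.null(ntPath)) {
        rawNt <- Biostrings::readBStringSet(ntPath)
        ntIds <- sub("\\s.*$", "", names(rawNt))
        if (anyDuplicated(ntIds)) {
            d <- ntIds[duplicated(ntIds)][1]
            stop("duplicate gene id '", d, "' in ", ntPath)
        }
        nt <- Biostrings::DNAStringSet(toupper(as.character(rawNt)))
        names(nt) <- ntIds
        nt <- nt[names(nt) %in% ids]
    }
    new("Proteome", genomeId = genomeId, aa = aa, nt = nt)
}

#' Read a directory of proteomes
#'
#' One FASTA file per genome (`.faa`/`.fasta`/`.fa`); optionally a second
#' directory with matching nucleotide FASTA files sharing the same file
#' stems.
#'
#' @param faaDir directory of amino-acid FASTA files.
#' @param ffnDir optional directory of nucleotide FASTA files.
#' @return named list of [Proteome-class] objects, sorted by genome id.
#' @export
readProteomeDir <- function(faaDir, ffnDir = NULL) {
    files <- sort(list.files(faaDir, pattern = "\\.(faa|fasta|fa)$",
                             full.names = TRUE))
    if (length(files) == 0L) stop("no FASTA files in ", faaDir)
    out <- lapply(files, function(f) {
        stem <- sub("\\.[^.]*$", "", basename(f))
        ntPath <- NULL
        if (!is.null(ffnDir)) {
            cand <- list.files(ffnDir, pattern = paste0("^", stem,
                               "\\.(ffn|fasta|fa|fna)$"), full.names = TRUE)
            if (length(cand)) ntPath <- cand[1]
        }
        readProteome(f, ntPath = ntPath)
    })
    names(out) <- vapply(out, function(p) p@genomeId, character(1))
    out
}

#' Write a proteome (and optionally its coding sequences) to FASTA
#' @param proteome a [Proteome-class].
#' @param path output amino-acid FASTA path.
#' @param ntPath optional output nucleotide FASTA path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(proteome, path, ntPath = NULL) {
    atomicWrite(path, function(tmp)
        Biostrings::writeXStringSet(proteome@aa, tmp))
    if (!is.null(ntPath) && !is.null(proteome@nt))
        atomicWrite(ntPath, function(tmp)
            Biostrings::writeXStringSet(proteome@nt, tmp))
    invisible(path)
}

#' Construct a Pangenome from gene/genome/orthogroup assignments
#'
#' @param gene,genome,orthogroup character vectors of equal length, or a
#'   3-column data.frame passed as `gene`.
#' @return a [Pangenome-class].
#' @export
Pangenome <- function(gene, genome = NULL, orthogroup = NULL) {
    if (is.data.frame(gene)) {
        df <- gene
        colnames(df) <- c("gene", "genome", "orthogroup")
    } else {
        df <- data.frame(gene = as.character(gene),
                         genome = as.character(genome),
                         orthogroup = as.character(orthogroup))
    }
    df[] <- lapply(df, as.character)
    rownames(df) <- NULL
    new("Pangenome", table = df)
}

#' Read a pangenome from a 3-column TSV
#'
#' Expects a headerless TSV with columns gene, genome, orthogroup.
#'
#' @param path TSV path.
#' @return a [Pangenome-class].
#' @export
readPangenome <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty pangenome file: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 3L)
    if (length(bad))
        stop("expected 3 tab-separated columns at line ", bad[1],
             " of ", path)
    m <- matrix(unlist(fields), ncol = 3, byrow = TRUE)
    Pangenome(m[, 1], m[, 2], m[, 3])
}

#' Write a pangenome as a 3-column TSV
#'
#' Written atomically (temp file + rename), tab-separated, no header, LF
#' line endings. `readPangenome(writePangenome(x))` reproduces `x` up to
#' row order.
#'
#' @param pangenome a [Pangenome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePangenome <- function(pangenome, path) {
    atomicWrite(path, function(tmp)
        write.table(pangenome@table, tmp, sep = "\t", quote = FALSE,
                    row.names = FALSE, col.names = FALSE, eol = "\n"))
}

# ---- accessors ----

#' @describeIn Proteome-class genome identifier
#' @param object,x a `Proteome`
#' @export
genomeId <- function(object) object@genomeId

#' @describeIn Proteome-class amino-acid sequences (AAStringSet)
#' @export
aaSeqs <- function(object) object@aa

#' @describeIn Proteome-class nucleotide sequences (DNAStringSet or NULL)
#' @export
ntSeqs <- function(object) object@nt

#' @export
setMethod("length", "Proteome", function(x) length(x@aa))

#' Pangenome accessors
#'
#' `panTable()` returns the underlying data.frame; `geneIds()`,
#' `genomeIds()` and `orthogroupIds()` the distinct identifiers.
#'
#' @param object a [Pangenome-class].
#' @return character vectors, or a data.frame for `panTable`.
#' @export
panTable <- function(object) object@table

#' @rdname panTable
#' @export
geneIds <- function(object) object@table$gene

#' @rdname panTable
#' @export
genomeIds <- function(object) sort(unique(object@table$genome))

#' @rdname panTable
#' @export
orthogroupIds <- function(object) sort(unique(object@table$orthogroup))

#' @export
setMethod("as.data.frame", "Pangenome",
          function(x, ...) x@table)

setMethod("show", "Proteome", function(object) {
    cat("Proteome", object@genomeId, "with", length(object@aa), "genes",
        if (!is.null(object@nt)) "(aa + nt)\n" else "(aa only)\n")
})

setMethod("show", "Pangenome", function(object) {
    tb <- object@table
    cat(sprintf("Pangenome: %d genes, %d genomes, %d orthogroups\n",
                nrow(tb), length(unique(tb$genome)),
                length(unique(tb$orthogroup))))
})

setMethod("show", "Profile", function(object) {
    cat(sprintf("Profile %s: %d columns (%d kept), %d sequences\n",
                object@orthogroupId, ncol(object@freq), sum(object@keep),
                object@nSeqs))
})

setMethod("show", "CoreProfile", function(object) {
    cat(sprintf("CoreProfile %s: %d kept columns, cutoff %.2f\n",
                object@orthogroupId, sum(object@keep), object@cutoff))
})

setMethod("show", "ProfileDB", function(object) {
    cat("ProfileDB with", length(object@profiles), "profiles\n")
})

setMethod("show", "SampleTrace", function(object) {
    cat("SampleTrace of", nrow(object@trace), "items;",
        object@nDistCalls, "distance evaluations\n")
})

setMethod("show", "PrevalenceModel", function(object) {
    cat(sprintf(paste0("PrevalenceModel: %d orthogroups, %d genomes, ",
                       "logLik %.2f (%d sweeps)\n"),
                length(object@q), length(object@c),
                object@logLik[length(object@logLik)],
                length(object@logLik)))
})

setMethod("show", "Supermatrix", function(object) {
    w <- if (length(object@aln)) Biostrings::width(object@aln)[1] else 0L
    cat(sprintf("Supermatrix: %d genomes x %d nt (%d blocks)\n",
                length(object@aln), w, nrow(object@blockMap)))
})

#' Construct a PanParams object
#'
#' Defaults follow the toolkit's published settings: 32 representatives,
#' 512 maximum sequences to align, 100 seed genomes, 90%/95% candidate and
#' final core prevalence.
#'
#' @param nReps,maxAlign,nSeedGenomes,candidateCorePrev,finalCorePrev,aniMethod,rngSeed,preclusterIdentity,superclusterFrac
#'   see [PanParams-class].
#' @return a [PanParams-class].
#' @export
PanParams <- function(nReps = 32L, maxAlign = 512L, nSeedGenomes = 100L,
                      candidateCorePrev = 0.90, finalCorePrev = 0.95,
                      aniMethod = "mean", rngSeed = 1L,
                      preclusterIdentity = 0.5, superclusterFrac = 0.25) {
    new("PanParams", nReps = as.integer(nReps),
        maxAlign = as.integer(maxAlign),
        nSeedGenomes = as.integer(nSeedGenomes),
        candidateCorePrev = candidateCorePrev,
        finalCorePrev = finalCorePrev, aniMethod = aniMethod,
        rngSeed = as.integer(rngSeed),
        preclusterIdentity = preclusterIdentity,
        superclusterFrac = superclusterFrac)
}

setMethod("show", "PanParams", function(object) {
    cat(sprintf(paste0("PanParams: nReps %d, maxAlign %d, seeds %d, ",
                       "corePrev %.2f/%.2f, ani %s, seed %d\n"),
                object@nReps, object@maxAlign, object@nSeedGenomes,
                object@candidateCorePrev, object@finalCorePrev,
                object@aniMethod, object@rngSeed))
})
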