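# Built-in sequence comparison engine: greedy k-mer preclustering,
# progressive multiple alignment, alignment profiles and local
# profile-sequence scoring. Fully deterministic; no external binaries.

#' Greedy k-mer preclustering of amino-acid sequences
#'
#' Genes are processed by decreasing length (ties broken by id); each gene
#' joins the earliest-founded precluster whose representative (its longest
#' member, the founder) shares a k-mer-estimated identity of at least
#' `minIdentity`, and founds a new precluster otherwise. The identity
#' estimate is the fraction of shared distinct k-mers relative to the
#' sequence with the smaller k-mer set; note that at 5-mers an estimate of
#' 0.5 corresponds to roughly 87% residue identity.
#'
#' @param seqs named character vector or [Biostrings::AAStringSet] of
#'   amino-acid sequences.
#' @param minIdentity minimum k-mer identity estimate to join a precluster.
#' @param k k-mer size (default 5).
#' @return list of character vectors of gene ids, one per precluster, in
#'   founding order. Every input gene occurs in exactly one precluster.
#' @export
precluster <- function(seqs, minIdentity = 0.5, k = 5L) {
    seqs <- asSeqVector(seqs)
    if (length(seqs) == 0L) stop("precluster needs at least one sequence")
    ord <- order(-nchar(seqs), names(seqs))
    s <- seqs[ord]
    assign <- preclusterCpp(unname(s), minIdentity, as.integer(k))
    unname(split(names(s), factor(assign, levels = seq_len(max(assign)))))
}

#' k-mer identity estimate between two sequences
#'
#' Fraction of shared distinct k-mers relative to the smaller k-mer set.
#' Monotone with (but numerically below) residue identity.
#'
#' @param a,b sequences (character).
#' @param k k-mer size.
#' @return fraction in \[0, 1\].
#' @export
kmerIdentity <- function(a, b, k = 5L) {
    kmerIdentityCpp(as.character(a), as.character(b), as.integer(k))
}

#' Multiple sequence alignment with the built-in progressive aligner
#'
#' Progressive alignment over a UPGMA guide tree built from pairwise k-mer
#' distances; groups are merged through a global (Needleman-Wunsch, affine
#' gaps, BLOSUM62) alignment of their longest members. Alignment quality
#' targets profile construction and within-family distances, not external
#' aligner fidelity.
#'
#' @param seqs named character vector or [Biostrings::AAStringSet]; a
#'   single sequence is returned as a 1-row alignment.
#' @return aligned [Biostrings::AAStringSet]; ungapping row i reproduces
#'   input i.
#' @export
alignSeqs <- function(seqs) {
    seqs <- asSeqVector(seqs)
    if (length(seqs) == 0L) stop("cannot align zero sequences")
    out <- if (length(seqs) == 1L) seqs else
        msaCpp(seqs, aaLookup(), AA_GAP_OPEN, AA_GAP_EXT, 5L)
    res <- Biostrings::AAStringSet(out)
    names(res) <- names(seqs)
    res
}

#' Global pairwise alignment
#'
#' Needleman-Wunsch with affine gaps (a gap of length L costs
#' `gapOpen + L * gapExt`). Used for per-gene identity in ANI computation
#' and inside the progressive aligner.
#'
#' @param a,b sequences (character).
#' @param type `"aa"` (BLOSUM62, 11/1) or `"nt"` (match 2 / mismatch -3,
#'   5/2).
#' @return list with `alignedA`, `alignedB`, `score`, and `identity`
#'   (matches over alignment columns).
#' @export
globalAlign <- function(a, b, type = c("aa", "nt")) {
    type <- match.arg(type)
    if (type == "aa")
        globalAlignCpp(as.character(a), as.character(b), aaLookup(),
                       AA_GAP_OPEN, AA_GAP_EXT)
    else
        globalAlignCpp(as.character(a), as.character(b), ntLookup(),
                       NT_GAP_OPEN, NT_GAP_EXT)
}

#' Build an alignment profile from an MSA
#'
#' Per alignment column, residue frequencies are
#' `(count + alpha) / (nrow + 20 * alpha)` over the 20 standard residues
#' (pseudocount `alpha = 0.1`); `X` and `*` contribute to the denominator
#' only. The consensus takes the most frequent residue per column
#' (alphabetical tie-break); columns with at least 50% gaps are dropped
#' from the consensus and from scoring.
#'
#' @param msa aligned sequences ([Biostrings::AAStringSet] or character),
#'   equal widths.
#' @param orthogroupId id recorded in the profile.
#' @param alpha pseudocount.
#' @return a [Profile-class].
#' @export
buildProfile <- function(msa, orthogroupId = "", alpha = 0.1) {
    msa <- asSeqVector(msa)
    if (length(msa) < 1L) stop("profile needs at least one aligned row")
    w <- nchar(msa)
    if (length(unique(w)) != 1L)
        stop("ragged alignment: row widths ", paste(unique(w),
             collapse = ", "))
    L <- w[1]
    n <- length(msa)
    chars <- matrix(unlist(strsplit(msa, "", fixed = TRUE), use.names = FALSE),
                    nrow = n, byrow = TRUE)
    counts <- vapply(seq_len(L), function(j)
        tabulate(match(chars[, j], AA20), nbins = 20L), integer(20))
    counts <- matrix(counts, nrow = 20L,
                     dimnames = list(AA20, NULL))
    freq <- (counts + alpha) / (n + 20 * alpha)
    gapFrac <- colSums(matrix(chars == "-", nrow = n)) / n
    keep <- gapFrac < 0.5
    consensus <- paste(AA20[apply(counts[, keep, drop = FALSE], 2,
                                  which.max)], collapse = "")
    new("Profile", orthogroupId = as.character(orthogroupId), freq = freq,
        keep = keep, consensus = consensus, nSeqs = n)
}

#' @describeIn buildProfile consensus sequence of a profile
#' @param profile a [Profile-class].
#' @export
consensusSeq <- function(profile) profile@consensus

# positional log2-odds matrix over residue codes 0..21 (cols 21/22 = X/*
# score 0), retained columns only
profileLogOdds <- function(profile) {
    f <- profile@freq[, profile@keep, drop = FALSE]
    lo <- t(log2(f / 0.05))
    cbind(lo, 0, 0)
}

#' Score a sequence against a profile
#'
#' Local (Smith-Waterman) alignment of the sequence against the profile's
#' retained columns, with per-column log2-odds match scores
#' (`log2(freq / (1/20))`) and affine gaps (11/1). Percent identity is
#' measured against the consensus over the aligned span.
#'
#' @param profile a [Profile-class].
#' @param seq amino-acid sequence (character); a trailing `*` is stripped.
#' @param target optional name recorded in the hit.
#' @return one-row data.frame: `query`, `target`, `score`, `pctIdentity`.
#' @export
scoreProfileSeq <- function(profile, seq, target = "") {
    s <- stripStop(toupper(as.character(seq)))
    if (!nzchar(s)) stop("cannot score an empty sequence")
    hit <- profileLocalAlignCpp(profileLogOdds(profile), profile@consensus,
                                s, AA_GAP_OPEN, AA_GAP_EXT)
    data.frame(query = profile@orthogroupId, target = as.character(target),
               score = hit$score, pctIdentity = hit$pctIdentity)
}

#' Symmetrised profile-profile score
#'
#' Scores each profile against the other's consensus and averages the two
#' local-alignment scores, so `scoreProfileProfile(p1, p2) ==
#' scoreProfileProfile(p2, p1)`.
#'
#' @param p1,p2 [Profile-class] objects.
#' @return numeric score.
#' @export
scoreProfileProfile <- function(p1, p2) {
    (scoreProfileSeq(p1, consensusSeq(p2))$score +
     scoreProfileSeq(p2, consensusSeq(p1))$score) / 2
}

# self-score of a profile (consensus scored against the profile)
profileSelfScore <- function(profile) {
    scoreProfileSeq(profile, consensusSeq(profile))$score
}

# internal: accept AAStringSet / DNAStringSet / character
asSeqVector <- function(x) {
    if (is(x, "XStringSet")) {
        out <- as.character(x)
        names(out) <- names(x)
        out
    } else if (is.character(x)) x
    else stop("expected sequences as character or XStringSet")
}

# batch profile search: profiles (list of Profile), seqs named character.
# Returns data.frame(gene, orthogroup, score, pctIdentity) for candidate
# pairs that share consensus k-mers (fraction >= minFrac).
searchProfiles <- function(profiles, seqs, minFrac = 0.05, k = 5L) {
    if (length(profiles) == 0L || length(seqs) == 0L)
        return(data.frame(gene = character(), orthogroup = character(),
                          score = numeric(), pctIdentity = numeric()))
    los <- lapply(profiles, profileLogOdds)
    cons <- vapply(profiles, consensusSeq, character(1))
    ids <- vapply(profiles, function(p) p@orthogroupId, character(1))
    hits <- profileSearchCpp(los, unname(cons), unname(seqs), as.integer(k),
                             minFrac, AA_GAP_OPEN, AA_GAP_EXT)
    data.frame(gene = names(seqs)[hits$seq], orthogroup = ids[hits$profile],
               score = hits$score, pctIdentity = hits$pctIdentity)
}
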