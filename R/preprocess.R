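#' @importFrom Biostrings DNAString reverseComplement translate subseq
NULL

#' Extract the usable protein fragment from a translated frame
#'
#' Mirrors transcript post-processing for translated expressed-sequence
#' contigs: the frame is split on `*` stop symbols and the longest
#' stop-free fragment is selected (ties resolved leftmost). If that
#' fragment is preceded by a stop codon in the frame, translation cannot
#' be assumed to start at its first residue, so the start is advanced to
#' the fragment's first methionine (the fragment is discarded when it has
#' none). Fragments shorter than `minLen` residues are discarded.
#'
#' @param frameSeq character scalar over amino-acid letters plus `*`.
#' @param minLen minimum fragment length to keep (default 60 residues).
#' @param metScanFirst apply the methionine-scan rule to every
#'   stop-preceded fragment *before* choosing the longest, instead of to
#'   the selected fragment only (the default).
#' @return the fragment as a character scalar, or `NA_character_` when no
#'   fragment survives the rules.
#' @examples
#' extractProteinFragment("MAKLMNPQRSTVW*AA", minLen = 4)
#' @export
extractProteinFragment <- function(frameSeq, minLen = 60L,
                                   metScanFirst = FALSE) {
    if (!nzchar(frameSeq)) stopf("empty translated frame")
    ch <- strsplit(toupper(frameSeq), "")[[1]]
    ok <- c(AA_STANDARD, AA_AMBIGUOUS, "*")
    if (any(!ch %in% ok))
        stopf("illegal character '%s' in translated frame",
              ch[which(!ch %in% ok)[1]])
    m <- gregexpr("[^*]+", frameSeq)[[1]]
    if (m[1] == -1L) return(NA_character_)
    starts <- as.integer(m)
    frags <- regmatches(frameSeq, gregexpr("[^*]+", frameSeq))[[1]]
    metScan <- function(frag) {
        pos <- regexpr("M", frag, fixed = TRUE)
        if (pos == -1L) NA_character_ else substring(frag, pos)
    }
    if (metScanFirst) {
        cand <- ifelse(starts > 1L, vapply(frags, metScan, character(1)), frags)
        keep <- !is.na(cand)
        if (!any(keep)) return(NA_character_)
        cand <- cand[keep]
        best <- cand[which.max(nchar(cand))]
    } else {
        sel <- which.max(nchar(frags))   # which.max is leftmost on ties
        best <- frags[sel]
        if (starts[sel] > 1L) best <- metScan(best)
        if (is.na(best)) return(NA_character_)
    }
    if (nchar(best) < minLen) return(NA_character_)
    unname(best)
}

#' Translate a nucleotide sequence in all six frames
#'
#' Standard genetic code; incomplete trailing codons are dropped and the
#' three reverse frames read the reverse complement. Codons containing N
#' translate to `X` unless the code resolves them unambiguously.
#'
#' @param nt nucleotide character scalar (A/C/G/T/N), length >= 3.
#' @return character vector of 6 translated frames, named
#'   `F1,F2,F3,R1,R2,R3`.
#' @examples
#' sixFrameTranslate("ATGAAA")
#' @export
sixFrameTranslate <- function(nt) {
    nt <- toupper(nt)
    ch <- strsplit(nt, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T", "N")))
        stopf("illegal nucleotide '%s'", ch[which(!ch %in% c("A","C","G","T","N"))[1]])
    if (nchar(nt) < 3L) stopf("need at least one full codon")
    fwd <- Biostrings::DNAString(nt)
    rev <- Biostrings::reverseComplement(fwd)
    tr1 <- function(x, off) {
        n <- length(x) - off
        n <- n - n %% 3L
        if (n < 3L) return("")
        as.character(Biostrings::translate(
            Biostrings::subseq(x, start = off + 1L, width = n),
            if.fuzzy.codon = "solve"))
    }
    out <- c(tr1(fwd, 0L), tr1(fwd, 1L), tr1(fwd, 2L),
             tr1(rev, 0L), tr1(rev, 1L), tr1(rev, 2L))
    names(out) <- c("F1", "F2", "F3", "R1", "R2", "R3")
    out
}

# Global pairwise identity: exact matches / alignment columns (end and
# internal gaps included), under match +1, mismatch 0, linear gap -1.
.pairIdentity <- function(a, b) {
    letters <- c(AA_STANDARD, AA_AMBIGUOUS, "*")
    mat <- diag(1, length(letters))
    dimnames(mat) <- list(letters, letters)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(a), Biostrings::AAString(b),
        type = "global", substitutionMatrix = mat,
        gapOpening = 0, gapExtension = 1)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    sum(pa == sa & pa != "-") / length(pa)
}

#' Greedy redundancy reduction by global sequence identity
#'
#' Deterministic greedy clustering of one species' proteome: records are
#' processed by decreasing length (ties by increasing id); each record
#' joins the first existing representative whose global pairwise identity
#' (exact matches over alignment columns, gaps included) reaches
#' `threshold`, otherwise it becomes a new representative. Length
#' difference between members is unrestricted.
#'
#' @param seqs named character vector or `AAStringSet` of one species'
#'   proteins.
#' @param threshold identity fraction in (0, 1]; default 0.98.
#' @return named character vector of representatives, in processing order.
#' @export
clusterByIdentity <- function(seqs, threshold = 0.98) {
    if (threshold <= 0 || threshold > 1)
        stopf("identity threshold must lie in (0, 1]")
    if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
    if (is.null(names(seqs))) names(seqs) <- sprintf("seq%d", seq_along(seqs))
    ord <- order(-nchar(seqs), names(seqs))
    seqs <- seqs[ord]
    reps <- character(0)
    for (i in seq_along(seqs)) {
        placed <- FALSE
        for (r in reps) {
            if (.pairIdentity(seqs[[i]], seqs[[r]]) >= threshold) {
                placed <- TRUE
                break
            }
        }
        if (!placed) reps <- c(reps, names(seqs)[i])
    }
    seqs[reps]
}
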