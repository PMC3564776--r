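# Sequence-composition thermostability measures.
#
# All percent-type measures use the effective length as denominator: the
# number of residues after removing the ambiguity letters B, Z, X, U, O.
# Ambiguity letters are excluded from numerators and denominators alike so
# percentages stay comparable across records of different ambiguity load.

.residueCounts <- function(seq) {
    ch <- strsplit(toupper(as.character(seq)), "")[[1]]
    bad <- which(!ch %in% c(AA_STANDARD, AA_AMBIGUOUS))
    if (length(bad))
        stopf("illegal residue '%s' at position %d", ch[bad[1]], bad[1])
    table(factor(ch[ch %in% AA_STANDARD], levels = AA_STANDARD))
}

#' Effective (ambiguity-free) length of a protein sequence
#'
#' @param seq protein sequence (character scalar or `AAString`).
#' @return integer count of standard residues.
#' @export
effectiveLength <- function(seq) {
    as.integer(sum(.residueCounts(seq)))
}

#' Amino-acid composition in percent
#'
#' @param seq protein sequence.
#' @return named numeric vector over the 20 standard residues, summing
#'   to 100.
#' @examples
#' aaFrequencies("MKKR")
#' @export
aaFrequencies <- function(seq) {
    n <- .residueCounts(seq)
    L <- sum(n)
    if (L == 0L) stopf("undefined composition: no standard residues")
    100 * as.numeric(n) / L -> p
    names(p) <- names(n)
    p
}

#' Charged-versus-polar bias (CvP-bias)
#'
#' `100 * (C - P) / L`, where C counts the charged residues E, D, K, R,
#' P the polar residues S, T, N, Q and L the effective length. Equal to
#' charged percent minus polar percent; higher values are associated with
#' thermostability.
#'
#' @param seq protein sequence.
#' @return CvP-bias in percentage points, in `[-100, 100]`.
#' @examples
#' cvpBias("MKDESTAA")  # charged 3, polar 2, length 8 -> 12.5
#' @export
cvpBias <- function(seq) {
    n <- .residueCounts(seq)
    L <- sum(n)
    if (L == 0L) stopf("undefined composition: no standard residues")
    100 * (sum(n[AA_CHARGED]) - sum(n[AA_POLAR])) / L
}

#' IVYWREL content
#'
#' Percent of residues in the set I, V, Y, W, R, E, L, a composition
#' statistic reported to track optimal growth temperature.
#'
#' @param seq protein sequence.
#' @return percent in `[0, 100]`.
#' @export
ivywrel <- function(seq) {
    n <- .residueCounts(seq)
    L <- sum(n)
    if (L == 0L) stopf("undefined composition: no standard residues")
    100 * sum(n[c("I", "V", "Y", "W", "R", "E", "L")]) / L
}

#' (E+K)/(Q+H) residue-count ratio
#'
#' A hyperthermophile discriminator. When the denominator Q+H is zero the
#' ratio is undefined and `NA` is returned (propagated as a missing value
#' in rankings, never as infinity).
#'
#' @param seq protein sequence.
#' @return non-negative ratio, or `NA_real_` when Q+H = 0.
#' @export
ekQhRatio <- function(seq) {
    n <- .residueCounts(seq)
    if (sum(n) == 0L) stopf("undefined composition: no standard residues")
    den <- sum(n[c("Q", "H")])
    if (den == 0L) return(NA_real_)
    sum(n[c("E", "K")]) / den
}

#' Serine content in percent
#'
#' @param seq protein sequence.
#' @return percent in `[0, 100]`; low serine content is associated with
#'   thermostability (direction -1 in the registry).
#' @export
serineContent <- function(seq) {
    n <- .residueCounts(seq)
    L <- sum(n)
    if (L == 0L) stopf("undefined composition: no standard residues")
    100 * n[["S"]] / L
}

#' Charged-residue (D, E, K, R) content in percent
#'
#' @param seq protein sequence.
#' @return percent in `[0, 100]`.
#' @export
chargedContent <- function(seq) {
    n <- .residueCounts(seq)
    L <- sum(n)
    if (L == 0L) stopf("undefined composition: no standard residues")
    100 * sum(n[AA_CHARGED]) / L
}

# Kyte-Doolittle hydropathy index.
.HYDROPATHY_SCALES <- list(
    KyteDoolittle = c(
        A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
        E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
        M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, V = 4.2,
        W = -0.9, Y = -1.3)
)

#' Mean hydropathy of a protein sequence
#'
#' Average of per-residue values from a named hydropathy scale, ambiguity
#' letters excluded.
#'
#' @param seq protein sequence.
#' @param scale scale name; `"KyteDoolittle"` is the only built-in.
#' @return mean per-residue hydropathy.
#' @examples
#' meanHydrophobicity("II")  # 4.5 on the Kyte-Doolittle scale
#' @export
meanHydrophobicity <- function(seq, scale = "KyteDoolittle") {
    if (!scale %in% names(.HYDROPATHY_SCALES))
        stopf("unknown hydropathy scale '%s'", scale)
    tab <- .HYDROPATHY_SCALES[[scale]]
    n <- .residueCounts(seq)
    L <- sum(n)
    if (L == 0L) stopf("undefined composition: no standard residues")
    sum(as.numeric(n) * tab[names(n)]) / L
}

#' GARP and FYMINK residue content
#'
#' Percent of residues encoded mainly by GC-rich codons (G, A, R, P) and
#' by AT-rich codons (F, Y, M, I, N, K); their ratio tracks genomic
#' GC-content and serves as a compositional confound diagnostic.
#'
#' @param seq protein sequence.
#' @return named numeric vector `c(garp =, fymink =)` of percents.
#' @export
garpFymink <- function(seq) {
    n <- .residueCounts(seq)
    L <- sum(n)
    if (L == 0L) stopf("undefined composition: no standard residues")
    c(garp = 100 * sum(n[c("G", "A", "R", "P")]) / L,
      fymink = 100 * sum(n[c("F", "Y", "M", "I", "N", "K")]) / L)
}

#' GC-content by codon position
#'
#' Splits an in-frame coding sequence into codons, drops codons containing
#' N entirely, and reports the percent of G/C at each codon position plus
#' the overall GC of the counted codons.
#'
#' @param codingSeq in-frame nucleotide sequence; length must be a
#'   multiple of 3.
#' @return list with elements `gc1`, `gc2`, `gc3`, `gc_total` (percents)
#'   and `n_codons` (codons counted).
#' @examples
#' gcByCodonPosition("ATGAAA")
#' @export
gcByCodonPosition <- function(codingSeq) {
    codingSeq <- toupper(as.character(codingSeq))
    ch <- strsplit(codingSeq, "")[[1]]
    if (any(!ch %in% c("A", "C", "G", "T", "N")))
        stopf("illegal nucleotide '%s'",
              ch[which(!ch %in% c("A","C","G","T","N"))[1]])
    if (length(ch) %% 3L != 0L)
        stopf("frame error: coding length %d is not a multiple of 3", length(ch))
    m <- matrix(ch, nrow = 3L)
    keep <- colSums(m == "N") == 0L
    m <- m[, keep, drop = FALSE]
    nc <- ncol(m)
    if (nc == 0L) stopf("no usable codons (all contain N)")
    isGC <- m == "G" | m == "C"
    gc <- 100 * rowSums(isGC) / nc
    list(gc1 = gc[1], gc2 = gc[2], gc3 = gc[3],
         gc_total = 100 * sum(isGC) / (3 * nc), n_codons = nc)
}

#' Built-in measure registry with thermophilic directions
#'
#' Direction +1 means larger values indicate more thermostable sequences,
#' -1 the opposite. Defaults: CvP-bias, IVYWREL, (E+K)/(Q+H), charged
#' content and mean hydropathy +1; serine content and trimmed length -1
#' (compact, low-serine proteins read as more thermoadapted).
#'
#' @return named numeric vector of +1/-1 over the built-in measures.
#' @export
builtinMeasures <- function() {
    c(cvp_bias = 1, ivywrel = 1, ek_qh = 1, serine = -1, charged = 1,
      hydrophobicity = 1, length = -1)
}

#' Evaluate all registered measures over a set of proteins
#'
#' Computes the built-in composition measures for every sequence and
#' merges external per-protein score tables (imported predictor outputs)
#' with their declared directions. Proteins missing from an external table
#' get `NA` for that measure.
#'
#' @param seqs named character vector or `AAStringSet`; species labels are
#'   taken from `mcols(seqs)$species` or the `species` argument.
#' @param species optional character vector (recycled) of species labels.
#' @param external list of `score_table` objects (see [scoreTable()]).
#' @param hydrophobicityScale scale name for the hydropathy measure.
#' @return a [MeasureTable-class] object.
#' @export
evaluateMeasures <- function(seqs, species = NULL, external = list(),
                             hydrophobicityScale = "KyteDoolittle") {
    if (methods::is(seqs, "XStringSet")) {
        if (is.null(species)) {
            mc <- S4Vectors::mcols(seqs)
            if (!is.null(mc) && "species" %in% colnames(mc))
                species <- as.character(mc$species)
        }
        seqs <- as.character(seqs)
    }
    if (is.null(names(seqs))) stopf("sequences must be named by protein id")
    if (anyDuplicated(names(seqs))) stopf("duplicate protein ids")
    if (is.null(species)) species <- rep(NA_character_, length(seqs))
    species <- rep_len(species, length(seqs))
    names(species) <- names(seqs)

    dirs <- builtinMeasures()
    extNames <- vapply(external, `[[`, character(1), "measure")
    clash <- intersect(extNames, names(dirs))
    if (length(clash))
        stopf("external measure '%s' collides with a built-in", clash[1])
    if (anyDuplicated(extNames)) stopf("duplicate external measure names")

    builtin <- t(vapply(seqs, function(s) {
        c(cvp_bias = cvpBias(s), ivywrel = ivywrel(s), ek_qh = ekQhRatio(s),
          serine = serineContent(s), charged = chargedContent(s),
          hydrophobicity = meanHydrophobicity(s, hydrophobicityScale),
          length = as.numeric(effectiveLength(s)))
    }, numeric(7)))
    vals <- builtin
    for (tab in external) {
        col <- unname(tab$scores[names(seqs)])
        vals <- cbind(vals, col)
        colnames(vals)[ncol(vals)] <- tab$measure
        dirs[tab$measure] <- tab$direction
    }
    effLen <- vapply(seqs, effectiveLength, integer(1))
    new("MeasureTable", values = vals, directions = dirs,
        effectiveLength = effLen, species = species)
}
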