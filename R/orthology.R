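# Reciprocal-best-hit orthology across S species.

#' Best cross-species hit per query and target species
#'
#' For every query protein and every target species, selects the subject
#' with maximal bitscore; ties are broken by lower evalue, then by the
#' lexicographically smallest subject id, so the result is deterministic.
#' Same-species hits are ignored.
#'
#' @param hits data.frame as returned by [readHitTable()] (columns
#'   `query_id`, `subject_id`, `query_species`, `subject_species`,
#'   `bitscore`, `evalue`).
#' @return data.frame with one row per (query, target species) pair:
#'   `query_id`, `query_species`, `target_species`, `subject_id`.
#' @export
bestHits <- function(hits) {
    hits <- hits[hits$query_species != hits$subject_species, , drop = FALSE]
    if (nrow(hits) == 0L)
        return(data.frame(query_id = character(), query_species = character(),
                          target_species = character(),
                          subject_id = character()))
    ord <- order(hits$query_id, hits$subject_species,
                 -hits$bitscore, hits$evalue, hits$subject_id)
    hits <- hits[ord, , drop = FALSE]
    key <- paste(hits$query_id, hits$subject_species, sep = "\r")
    first <- !duplicated(key)
    data.frame(
        query_id = hits$query_id[first],
        query_species = hits$query_species[first],
        target_species = hits$subject_species[first],
        subject_id = hits$subject_id[first],
        stringsAsFactors = FALSE)
}

#' Build fully consistent reciprocal-best-hit orthologous sets
#'
#' An orthologous set is one protein per species such that for *every*
#' ordered species pair (A, B) the best hit of the member from A in
#' species B is exactly the member from B — the strictest reading of
#' best-hit consistency across all pairwise searches (mode `"clique"`).
#' Mode `"star"` relaxes this to reciprocity between the seed species and
#' each other species only. Construction seeds from each protein of the
#' first species in `speciesOrder` and verifies closure; output is sorted
#' by seed protein id and each protein appears in at most one set.
#'
#' @param best best-hit table from [bestHits()].
#' @param speciesOrder character vector of all species in the run (no
#'   duplicates); the first entry is the seed species.
#' @param mode `"clique"` (default, full consistency) or `"star"`.
#' @return named list of orthologous sets; each element is a character
#'   vector `species -> protein id`, named by its seed protein.
#' @export
buildOrthologSets <- function(best, speciesOrder,
                              mode = c("clique", "star")) {
    mode <- match.arg(mode)
    if (anyDuplicated(speciesOrder))
        stopf("duplicated species in speciesOrder")
    if (length(speciesOrder) < 2L) stopf("need at least two species")
    bh <- stats::setNames(best$subject_id,
                          paste(best$query_id, best$target_species,
                                sep = "\r"))
    lookup <- function(id, sp) {
        v <- bh[paste(id, sp, sep = "\r")]
        if (is.na(v)) NA_character_ else unname(v)
    }
    seedSp <- speciesOrder[1]
    others <- speciesOrder[-1]
    seeds <- sort(unique(best$query_id[best$query_species == seedSp]))
    used <- character(0)
    sets <- list()
    for (seed in seeds) {
        members <- c(stats::setNames(seed, seedSp),
                     stats::setNames(vapply(others, function(sp)
                         lookup(seed, sp), character(1)), others))
        if (anyNA(members)) next
        okPairs <- if (mode == "clique") {
            all(vapply(speciesOrder, function(a) {
                all(vapply(setdiff(speciesOrder, a), function(b)
                    identical(lookup(members[[a]], b), members[[b]]),
                    logical(1)))
            }, logical(1)))
        } else {
            all(vapply(others, function(b)
                identical(lookup(members[[b]], seedSp), seed), logical(1)))
        }
        if (!okPairs) next
        if (any(members %in% used)) next
        used <- c(used, members)
        sets[[seed]] <- members
    }
    if (length(sets)) sets[order(names(sets))] else sets
}

#' Trim an alignment to its shared gap-free core
#'
#' Finds the leftmost and rightmost alignment columns that are gap-free in
#' every row and restricts each row to that span, removing any interior
#' gaps, so every sequence is represented by the homologous fragment.
#' Fragment lengths may still differ through interior gaps.
#'
#' @param alignedRows named character vector of equal-width gapped rows
#'   (gap symbol `-`), at least 2 rows.
#' @return list with `span` (`c(first, last)`, 1-based inclusive columns)
#'   and `fragments` (named character vector of ungapped fragments).
#' @examples
#' trimAlignment(c(a = "--KDE-R", b = "MAKDEFR"))
#' @export
trimAlignment <- function(alignedRows) {
    if (length(alignedRows) < 2L) stopf("need at least two aligned rows")
    w <- unique(nchar(alignedRows))
    if (length(w) != 1L) stopf("aligned rows differ in width")
    mat <- do.call(rbind, strsplit(alignedRows, ""))
    gapFree <- which(colSums(mat == "-") == 0L)
    if (length(gapFree) == 0L)
        stopf("untrimmable alignment: no gap-free column")
    span <- c(first = min(gapFree), last = max(gapFree))
    frags <- vapply(seq_len(nrow(mat)), function(i) {
        piece <- mat[i, span[1]:span[2]]
        paste(piece[piece != "-"], collapse = "")
    }, character(1))
    names(frags) <- names(alignedRows)
    list(span = span, fragments = frags)
}
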