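# Species ranking per orthologous set, cumulative rank sums, and ROC
# discrimination of thermophile/mesophile protein sets.

#' Rank species within one orthologous set
#'
#' Rank 1 is the most thermostable species under the measure's direction
#' (direction +1: largest value first). Ties receive the average of the
#' tied rank positions. Missing values receive no rank.
#'
#' @param values named numeric vector, species -> measure value (may
#'   contain `NA`).
#' @param direction +1 or -1 (the measure's thermophilic direction).
#' @return named numeric vector of ranks over the non-missing species, or
#'   `NULL` when fewer than 2 values are present (skip signal).
#' @examples
#' rankSet(c(A = 10, B = 5, C = 1), direction = 1)
#' @export
rankSet <- function(values, direction = 1) {
    if (!direction %in% c(-1, 1)) stopf("direction must be +1 or -1")
    ok <- !is.na(values)
    if (sum(ok) < 2L) return(NULL)
    rank(-direction * values[ok], ties.method = "average")
}

#' Species-by-measure matrix of one orthologous set
#'
#' Reshapes a [MeasureTable-class] whose rows are the members of a single
#' orthologous set (one protein per species) into a species x measure
#' matrix, the unit consumed by [cumulativeRanks()].
#'
#' @param mt a [MeasureTable-class] with one protein per species.
#' @return numeric matrix, species in rows, measures in columns.
#' @export
setMeasureMatrix <- function(mt) {
    sp <- proteinSpecies(mt)
    if (anyNA(sp)) stopf("all proteins need species labels")
    if (anyDuplicated(sp)) stopf("more than one protein for species '%s'",
                                 sp[which(duplicated(sp))[1]])
    v <- measureValues(mt)
    rownames(v) <- unname(sp)
    v
}

#' Cumulative rank sums over orthologous sets
#'
#' For each measure, species are ranked within every usable set and the
#' ranks summed. A set is usable for a measure only when every species has
#' a non-missing value (sets with any missing value are excluded rather
#' than re-ranked over a subset, keeping sums comparable across species).
#' Conservation: each summary's ranks sum to `nSetsUsed * S(S+1)/2`.
#'
#' @param setMatrices list of species x measure matrices (see
#'   [setMeasureMatrix()]), all with the same species rows.
#' @param directions named numeric vector of +1/-1 per measure; defaults
#'   to [builtinMeasures()] restricted to the available columns.
#' @return named list of [RankSummary-class] objects, one per measure.
#' @export
cumulativeRanks <- function(setMatrices, directions = NULL) {
    if (length(setMatrices) == 0L) stopf("no orthologous sets supplied")
    species <- rownames(setMatrices[[1]])
    measures <- colnames(setMatrices[[1]])
    if (is.null(directions)) {
        directions <- builtinMeasures()
        directions <- directions[intersect(names(directions), measures)]
    }
    measures <- intersect(measures, names(directions))
    if (length(measures) == 0L) stopf("no measure has a registered direction")
    out <- lapply(measures, function(m) {
        total <- stats::setNames(numeric(length(species)), species)
        used <- 0L
        for (mat in setMatrices) {
            v <- mat[species, m]
            if (anyNA(v)) next
            r <- rankSet(stats::setNames(v, species), directions[[m]])
            if (is.null(r) || length(r) < length(species)) next
            total[names(r)] <- total[names(r)] + r
            used <- used + 1L
        }
        new("RankSummary", measure = m, cumulativeRank = total,
            nSetsUsed = used)
    })
    stats::setNames(out, measures)
}

#' ROC curve and AUC for labelled thermostability scores
#'
#' Scores are oriented by the measure's direction so that larger oriented
#' scores indicate the positive (thermophile) class, then swept over all
#' unique values to trace the ROC curve. The AUC is computed by the
#' rank/pair method — the fraction of (positive, negative) pairs ordered
#' correctly, ties counting one half — which equals the trapezoidal area
#' under the traced curve.
#'
#' @param scores numeric measure values.
#' @param labels character class labels, same length; exactly two classes.
#' @param positive label of the positive (thermophile) class.
#' @param direction +1 or -1; scores are multiplied by it before the sweep.
#' @return a [RocResult-class] object.
#' @examples
#' rocAuc(c(2, 3, 0, 1), c("t", "t", "m", "m"), positive = "t")
#' @export
rocAuc <- function(scores, labels, positive = "thermophile", direction = 1) {
    if (length(scores) != length(labels)) stopf("scores/labels length mismatch")
    labels <- as.character(labels)
    if (!positive %in% labels || all(labels == positive))
        stopf("undefined ROC: both classes must be present")
    ok <- !is.na(scores)
    scores <- scores[ok]; labels <- labels[ok]
    s <- direction * scores
    pos <- labels == positive
    nPos <- sum(pos); nNeg <- sum(!pos)
    # Mann-Whitney rank form of pair counting (ties contribute 1/2)
    r <- rank(s, ties.method = "average")
    aucVal <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    thr <- sort(unique(s), decreasing = TRUE)
    tp <- vapply(thr, function(t) sum(s >= t & pos), numeric(1))
    fp <- vapply(thr, function(t) sum(s >= t & !pos), numeric(1))
    pts <- cbind(fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos))
    if (any(pts[nrow(pts), ] != c(1, 1))) pts <- rbind(pts, c(1, 1))
    new("RocResult", scores = unname(s), labels = labels,
        positive = positive, rocPoints = pts, auc = aucVal)
}

#' Pair-level concordance of homologous thermophile/mesophile pairs
#'
#' The fraction of homolog pairs in which the thermophilic member scores
#' strictly higher than its mesophilic partner under the measure's
#' direction; ties count one half.
#'
#' @param thermoValues,mesoValues numeric vectors of equal length, one
#'   entry per homolog pair.
#' @param direction +1 or -1.
#' @return fraction in `[0, 1]`.
#' @export
pairedConcordance <- function(thermoValues, mesoValues, direction = 1) {
    if (length(thermoValues) != length(mesoValues) || length(thermoValues) < 1L)
        stopf("need equal-length, non-empty pair vectors")
    d <- direction * (thermoValues - mesoValues)
    (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
}
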