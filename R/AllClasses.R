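#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' MeasureTable: per-protein values for named thermostability measures
#'
#' A matrix-like container holding one row per protein and one column per
#' registered measure, together with each measure's thermophilic direction
#' (+1 if larger values indicate a more thermostable protein, -1 otherwise),
#' the effective (ambiguity-free) length of every protein, and the species
#' label of every protein.
#'
#' @slot values numeric matrix, proteins x measures; `NA` marks a missing
#'   (e.g. undefined-ratio or unscored-external) value.
#' @slot directions named numeric vector over the measure columns, each
#'   entry +1 or -1.
#' @slot effectiveLength named integer vector, one entry per protein row:
#'   sequence length after removing ambiguity letters (B, Z, X, U, O).
#' @slot species named character vector, one entry per protein row.
#'
#' @seealso [evaluateMeasures()], [measureValues()], [measureDirections()]
#' @exportClass MeasureTable
setClass("MeasureTable",
    representation(
        values = "matrix",
        directions = "numeric",
        effectiveLength = "integer",
        species = "character"
    )
)

setValidity("MeasureTable", function(object) {
    v <- object@values
    msgs <- character()
    if (!is.numeric(v)) msgs <- c(msgs, "'values' must be a numeric matrix")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msgs <- c(msgs, "'values' must have row (protein) and column (measure) names")
    if (!identical(sort(names(object@directions)), sort(colnames(v))))
        msgs <- c(msgs, "every measure column needs a direction and vice versa")
    if (!all(object@directions %in% c(-1, 1)))
        msgs <- c(msgs, "directions must be +1 or -1")
    if (!identical(names(object@effectiveLength), rownames(v)))
        msgs <- c(msgs, "'effectiveLength' must be named by the protein rows")
    if (!identical(names(object@species), rownames(v)))
        msgs <- c(msgs, "'species' must be named by the protein rows")
    cvp <- intersect("cvp_bias", colnames(v))
    if (length(cvp)) {
        x <- v[, cvp]
        if (any(!is.na(x) & (x < -100 | x > 100)))
            msgs <- c(msgs, "cvp_bias values must lie in [-100, 100]")
    }
    if (length(msgs)) msgs else TRUE
})

#' RankSummary: cumulative species ranks for one measure
#'
#' Per-measure cumulative rank sums over a collection of orthologous sets.
#' Within each usable set, species are ranked 1 (most thermostable under the
#' measure's direction) to S, ties sharing the average rank; the summary is
#' the sum of those ranks across all usable sets. Conservation invariant:
#' the ranks sum to `nSetsUsed * S * (S + 1) / 2`.
#'
#' @slot measure single measure name.
#' @slot cumulativeRank named numeric vector, species -> summed rank.
#' @slot nSetsUsed number of orthologous sets that contributed (sets with
#'   any missing species value are skipped for the measure).
#'
#' @seealso [cumulativeRanks()]
#' @exportClass RankSummary
setClass("RankSummary",
    representation(
        measure = "character",
        cumulativeRank = "numeric",
        nSetsUsed = "integer"
    )
)

setValidity("RankSummary", function(object) {
    s <- length(object@cumulativeRank)
    if (length(object@measure) != 1L) return("'measure' must be length 1")
    if (is.null(names(object@cumulativeRank)))
        return("'cumulativeRank' must be named by species")
    if (object@nSetsUsed > 0L && s >= 2L) {
        want <- object@nSetsUsed * s * (s + 1) / 2
        if (abs(sum(object@cumulativeRank) - want) > 1e-8)
            return(sprintf(
                "rank-sum conservation violated: sum %.6f != nSetsUsed * S(S+1)/2 = %.6f",
                sum(object@cumulativeRank), want))
    }
    TRUE
})

#' RocResult: ROC points and AUC for a labelled score set
#'
#' @slot scores numeric score vector (oriented so larger means more
#'   thermophile-like).
#' @slot labels character vector, same length, two classes.
#' @slot positive the label treated as positive (thermophile).
#' @slot rocPoints two-column matrix (fpr, tpr) from (0,0) to (1,1),
#'   monotone non-decreasing in both coordinates.
#' @slot auc area under the curve, computed by the rank/pair method
#'   (equals the trapezoidal area of `rocPoints`).
#'
#' @seealso [rocAuc()]
#' @exportClass RocResult
setClass("RocResult",
    representation(
        scores = "numeric",
        labels = "character",
        positive = "character",
        rocPoints = "matrix",
        auc = "numeric"
    )
)

setValidity("RocResult", function(object) {
    p <- object@rocPoints
    msgs <- character()
    if (ncol(p) != 2L) msgs <- c(msgs, "'rocPoints' needs columns (fpr, tpr)")
    if (nrow(p) >= 1L) {
        if (any(abs(p[1, ] - c(0, 0)) > 1e-12) ||
            any(abs(p[nrow(p), ] - c(1, 1)) > 1e-12))
            msgs <- c(msgs, "'rocPoints' must run from (0,0) to (1,1)")
        if (any(diff(p[, 1]) < -1e-12) || any(diff(p[, 2]) < -1e-12))
            msgs <- c(msgs, "'rocPoints' must be monotone non-decreasing")
    }
    if (object@auc < -1e-12 || object@auc > 1 + 1e-12)
        msgs <- c(msgs, "'auc' must lie in [0, 1]")
    if (length(msgs)) msgs else TRUE
})

#' MeltCurve: one thermal-shift fluorescence series
#'
#' @slot temperatures strictly increasing temperature grid in degrees C.
#' @slot fluorescence fluorescence readings, same length.
#' @slot wellId well identifier.
#'
#' @seealso [fitTm()], [readMeltPlate()], [genMeltCurve()]
#' @exportClass MeltCurve
setClass("MeltCurve",
    representation(
        temperatures = "numeric",
        fluorescence = "numeric",
        wellId = "character"
    )
)

setValidity("MeltCurve", function(object) {
    msgs <- character()
    if (length(object@temperatures) < 10L)
        msgs <- c(msgs, "a melt curve needs at least 10 points")
    if (length(object@temperatures) != length(object@fluorescence))
        msgs <- c(msgs, "temperature and fluorescence vectors differ in length")
    if (any(diff(object@temperatures) <= 0))
        msgs <- c(msgs, "temperatures must be strictly increasing")
    if (length(msgs)) msgs else TRUE
})

#' BoltzmannFit: fitted Boltzmann unfolding transition
#'
#' Parameters of the sigmoid
#' \eqn{f(T) = f_{low} + (f_{high} - f_{low}) / (1 + \exp((T_m - T)/a))},
#' where `tm` is the unfolding midpoint and `slopeA` the transition width
#' (degrees C).
#'
#' @slot tm melting temperature (degrees C).
#' @slot slopeA transition slope parameter (degrees C).
#' @slot fLow,fHigh folded / unfolded baseline fluorescence.
#' @slot rss residual sum of squares over the fitted region.
#' @slot converged logical convergence flag.
#' @slot reliable logical; FALSE when the fitted tm falls outside the
#'   observed temperature range (reported with a warning).
#'
#' @seealso [fitTm()], [boltzmannModel()]
#' @exportClass BoltzmannFit
setClass("BoltzmannFit",
    representation(
        tm = "numeric",
        slopeA = "numeric",
        fLow = "numeric",
        fHigh = "numeric",
        rss = "numeric",
        converged = "logical",
        reliable = "logical"
    )
)

#' CorrelationResult: Pearson correlation with least-squares line
#'
#' @slot r product-moment correlation coefficient.
#' @slot pValue two-sided p-value from the t transform on n - 2 df.
#' @slot n sample size.
#' @slot slope,intercept ordinary least-squares line of y on x.
#' @slot slopeCI95 two-sided 95 percent confidence interval for the slope.
#'
#' @seealso [pearsonCor()]
#' @exportClass CorrelationResult
setClass("CorrelationResult",
    representation(
        r = "numeric",
        pValue = "numeric",
        n = "integer",
        slope = "numeric",
        intercept = "numeric",
        slopeCI95 = "numeric"
    )
)

setValidity("CorrelationResult", function(object) {
    if (abs(object@r) > 1 + 1e-12) return("|r| must be <= 1")
    TRUE
})

# ---- show methods ----------------------------------------------------------

setMethod("show", "MeasureTable", function(object) {
    cat(sprintf("MeasureTable: %d proteins x %d measures\n",
        nrow(object@values), ncol(object@values)))
    cat("  measures:",
        paste(sprintf("%s(%+d)", colnames(object@values),
            as.integer(object@directions[colnames(object@values)])),
            collapse = ", "), "\n")
    cat("  species: ", paste(unique(object@species), collapse = ", "), "\n",
        sep = "")
    nmiss <- sum(is.na(object@values))
    if (nmiss) cat("  missing cells:", nmiss, "\n")
})

setMethod("show", "RankSummary", function(object) {
    cat(sprintf("RankSummary for '%s' over %d sets\n",
        object@measure, object@nSetsUsed))
    print(sort(object@cumulativeRank))
})

setMethod("show", "RocResult", function(object) {
    cat(sprintf("RocResult: %d scores (%d positive '%s'), AUC = %.4f\n",
        length(object@scores), sum(object@labels == object@positive),
        object@positive, object@auc))
})

setMethod("show", "MeltCurve", function(object) {
    cat(sprintf("MeltCurve '%s': %d points, %.1f-%.1f degC\n",
        object@wellId, length(object@temperatures),
        min(object@temperatures), max(object@temperatures)))
})

setMethod("show", "BoltzmannFit", function(object) {
    cat(sprintf(
        "BoltzmannFit: Tm = %.2f degC, slope = %.3f, baselines [%.1f, %.1f]\n",
        object@tm, object@slopeA, object@fLow, object@fHigh))
    cat(sprintf("  rss = %.4g, converged = %s, reliable = %s\n",
        object@rss, object@converged, object@reliable))
})

setMethod("show", "CorrelationResult", function(object) {
    cat(sprintf("CorrelationResult: r = %.3f, p = %.3g, n = %d\n",
        object@r, object@pValue, object@n))
    cat(sprintf("  y = %.4g + %.4g x; slope 95%% CI [%.4g, %.4g]\n",
        object@intercept, object@slope,
        object@slopeCI95[1], object@slopeCI95[2]))
})
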