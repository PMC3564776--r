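# Accessor generics and methods for the core classes. Slot access from user
# code should always go through these.

#' Extract the protein-by-measure value matrix
#'
#' @param x a [MeasureTable-class] object.
#' @return numeric matrix, proteins in rows, measures in columns.
#' @export
setGeneric("measureValues", function(x) standardGeneric("measureValues"))

#' @rdname measureValues
setMethod("measureValues", "MeasureTable", function(x) x@values)

#' Thermophilic direction of each measure
#'
#' @param x a [MeasureTable-class] object.
#' @return named numeric vector of +1/-1 per measure.
#' @export
setGeneric("measureDirections", function(x) standardGeneric("measureDirections"))

#' @rdname measureDirections
setMethod("measureDirections", "MeasureTable", function(x) x@directions)

#' Effective (ambiguity-free) protein lengths
#'
#' @param x a [MeasureTable-class] object.
#' @return named integer vector per protein.
#' @export
setGeneric("effectiveLengths", function(x) standardGeneric("effectiveLengths"))

#' @rdname effectiveLengths
setMethod("effectiveLengths", "MeasureTable", function(x) x@effectiveLength)

#' Species label of each protein row
#'
#' @param x a [MeasureTable-class] object.
#' @return named character vector per protein.
#' @export
setGeneric("proteinSpecies", function(x) standardGeneric("proteinSpecies"))

#' @rdname proteinSpecies
setMethod("proteinSpecies", "MeasureTable", function(x) x@species)

#' Cumulative rank sums of a RankSummary
#'
#' @param x a [RankSummary-class] object.
#' @return named numeric vector, species -> cumulative rank.
#' @export
setGeneric("cumulativeRank", function(x) standardGeneric("cumulativeRank"))

#' @rdname cumulativeRank
setMethod("cumulativeRank", "RankSummary", function(x) x@cumulativeRank)

#' Number of orthologous sets used by a RankSummary
#'
#' @param x a [RankSummary-class] object.
#' @return integer count of usable sets.
#' @export
setGeneric("nSetsUsed", function(x) standardGeneric("nSetsUsed"))

#' @rdname nSetsUsed
setMethod("nSetsUsed", "RankSummary", function(x) x@nSetsUsed)

#' Area under the ROC curve
#'
#' @param x a [RocResult-class] object.
#' @return AUC in `[0, 1]`.
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname auc
setMethod("auc", "RocResult", function(x) x@auc)

#' ROC curve points
#'
#' @param x a [RocResult-class] object.
#' @return two-column matrix with columns `fpr` and `tpr`.
#' @export
setGeneric("rocPoints", function(x) standardGeneric("rocPoints"))

#' @rdname rocPoints
setMethod("rocPoints", "RocResult", function(x) x@rocPoints)

#' Temperatures of a melt curve
#'
#' @param x a [MeltCurve-class] object.
#' @return numeric vector in degrees C.
#' @export
setGeneric("curveTemperatures", function(x) standardGeneric("curveTemperatures"))

#' @rdname curveTemperatures
setMethod("curveTemperatures", "MeltCurve", function(x) x@temperatures)

#' Fluorescence readings of a melt curve
#'
#' @param x a [MeltCurve-class] object.
#' @return numeric vector.
#' @export
setGeneric("curveFluorescence", function(x) standardGeneric("curveFluorescence"))

#' @rdname curveFluorescence
setMethod("curveFluorescence", "MeltCurve", function(x) x@fluorescence)

#' Well identifier of a melt curve
#'
#' @param x a [MeltCurve-class] object.
#' @return character scalar.
#' @export
setGeneric("wellId", function(x) standardGeneric("wellId"))

#' @rdname wellId
setMethod("wellId", "MeltCurve", function(x) x@wellId)

#' Fitted melting temperature
#'
#' @param x a [BoltzmannFit-class] object.
#' @return Tm in degrees C.
#' @export
setGeneric("meltingTemperature", function(x) standardGeneric("meltingTemperature"))

#' @rdname meltingTemperature
setMethod("meltingTemperature", "BoltzmannFit", function(x) x@tm)

#' Fitted Boltzmann parameters as a named vector
#'
#' @param x a [BoltzmannFit-class] object.
#' @return named numeric vector `(tm, slope_a, f_low, f_high, rss)`.
#' @export
setGeneric("fitParameters", function(x) standardGeneric("fitParameters"))

#' @rdname fitParameters
setMethod("fitParameters", "BoltzmannFit", function(x) {
    c(tm = x@tm, slope_a = x@slopeA, f_low = x@fLow, f_high = x@fHigh,
      rss = x@rss)
})

#' Pearson correlation coefficient of a CorrelationResult
#'
#' @param x a [CorrelationResult-class] object.
#' @return numeric scalar r.
#' @export
setGeneric("corCoefficient", function(x) standardGeneric("corCoefficient"))

#' @rdname corCoefficient
setMethod("corCoefficient", "CorrelationResult", function(x) x@r)

#' Two-sided p-value of a CorrelationResult
#'
#' @param x a [CorrelationResult-class] object.
#' @return numeric scalar p.
#' @export
setGeneric("corPValue", function(x) standardGeneric("corPValue"))

#' @rdname corPValue
setMethod("corPValue", "CorrelationResult", function(x) x@pValue)

#' Least-squares line of a CorrelationResult
#'
#' @param x a [CorrelationResult-class] object.
#' @return named numeric vector `(intercept, slope, slope_lo, slope_hi)`.
#' @export
setGeneric("corLine", function(x) standardGeneric("corLine"))

#' @rdname corLine
setMethod("corLine", "CorrelationResult", function(x) {
    c(intercept = x@intercept, slope = x@slope,
      slope_lo = x@slopeCI95[1], slope_hi = x@slopeCI95[2])
})
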