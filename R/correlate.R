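# Correlation stages: proteome means vs phenotype, GC-confound checks,
# and concordance of measure differences with melting-temperature
# differences in orthologous protein pairs.

#' Pearson correlation with least-squares line
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform on n - 2 degrees of freedom, plus the ordinary least-squares
#' line of `y` on `x` and a 95 percent confidence interval for its slope.
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return a [CorrelationResult-class] object.
#' @examples
#' pearsonCor(1:10, 2 * (1:10) + 1)
#' @export
pearsonCor <- function(x, y) {
    if (length(x) != length(y)) stopf("x and y must have equal length")
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) stopf("need at least 3 complete pairs")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stopf("degenerate input: zero variance")
    ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
    fit <- stats::lm(y ~ x)
    # suppress the "essentially perfect fit" note on exactly collinear input
    ci <- suppressWarnings(stats::confint(fit, level = 0.95))["x", ]
    new("CorrelationResult",
        r = unname(ct$estimate), pValue = ct$p.value, n = length(x),
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        slopeCI95 = unname(ci))
}

#' Per-species unweighted mean of a measure
#'
#' @param mt a [MeasureTable-class] with species labels.
#' @param measure measure column name.
#' @return named numeric vector, species -> mean over its proteins
#'   (missing values dropped per species).
#' @export
speciesMeans <- function(mt, measure) {
    v <- measureValues(mt)
    if (!measure %in% colnames(v)) stopf("unknown measure '%s'", measure)
    sp <- proteinSpecies(mt)
    if (anyNA(sp)) stopf("all proteins need species labels")
    tapply(v[, measure], sp, mean, na.rm = TRUE)
}

#' Correlate per-species proteome means with body temperature
#'
#' @param means named numeric vector of per-species proteome means (see
#'   [speciesMeans()]), unweighted by protein length.
#' @param phenotype named numeric vector, species -> body temperature in
#'   degrees C (see [readPhenotypeTable()]).
#' @return a [CorrelationResult-class]; x is body temperature, y the
#'   proteome mean.
#' @export
proteomeMeanVsPhenotype <- function(means, phenotype) {
    common <- intersect(names(means), names(phenotype))
    if (length(common) < 3L)
        stopf("insufficient overlap: only %d species shared", length(common))
    pearsonCor(unname(phenotype[common]), unname(means[common]))
}

#' Correlate per-species measure means with third-position GC
#'
#' Confound check: a thermostability measure driven by genomic GC-content
#' would correlate with GC3 across species.
#'
#' @param means named numeric vector of per-species measure means.
#' @param gc3 named numeric vector of per-species GC3 percents.
#' @return a [CorrelationResult-class]; x is GC3, y the measure mean.
#' @export
measureVsGc3 <- function(means, gc3) {
    common <- intersect(names(means), names(gc3))
    if (length(common) < 3L)
        stopf("insufficient overlap: only %d species shared", length(common))
    pearsonCor(unname(gc3[common]), unname(means[common]))
}

#' Read a thermophile/mesophile ortholog-pair stability table
#'
#' Tab-separated with a header line and columns: protein, thermophilic
#' measure value, mesophilic measure value, thermophilic Tm, mesophilic
#' Tm. Tm entries may be ranges like `45-46`; the midpoint is used as the
#' scalar value and the printed range is retained.
#'
#' @param path TSV path.
#' @return data.frame with columns `protein`, `thermo_value`,
#'   `meso_value`, `thermo_tm`, `meso_tm` (scalars), `thermo_tm_printed`,
#'   `meso_tm_printed`, and `difference` (= meso_value - thermo_value).
#' @export
readStabilityPairs <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(tab) < 5L)
        stopf("pair table needs protein, two measure and two Tm columns")
    asTm <- function(s) {
        # temperatures are positive degC, so '-' between digits is a range
        vapply(s, function(one) {
            nums <- as.numeric(regmatches(one,
                gregexpr("[0-9]+\\.?[0-9]*", one))[[1]])
            if (!length(nums)) return(NA_real_)
            if (length(nums) >= 2 && grepl("[0-9]\\s*-\\s*[0-9]", one))
                mean(nums[1:2]) else nums[1]
        }, numeric(1), USE.NAMES = FALSE)
    }
    data.frame(
        protein = as.character(tab[[1]]),
        thermo_value = as.numeric(tab[[2]]),
        meso_value = as.numeric(tab[[3]]),
        thermo_tm = asTm(as.character(tab[[4]])),
        meso_tm = asTm(as.character(tab[[5]])),
        thermo_tm_printed = as.character(tab[[4]]),
        meso_tm_printed = as.character(tab[[5]]),
        difference = as.numeric(tab[[3]]) - as.numeric(tab[[2]]),
        stringsAsFactors = FALSE)
}

#' Sign concordance of measure and Tm differences across ortholog pairs
#'
#' Both differences use the mesophilic - thermophilic convention. A pair
#' is concordant when the two differences share the same (non-zero) sign;
#' zero differences count as discordant and are flagged. Pairs without a
#' Tm value are skipped with a warning.
#'
#' @param pairs data.frame as from [readStabilityPairs()] (columns
#'   `thermo_value`, `meso_value`, `thermo_tm`, `meso_tm`; optional
#'   `protein`).
#' @return list with `nConcordant`, `nTotal`, and a per-pair data.frame
#'   `detail` (`difference_value`, `difference_tm`, `concordant`,
#'   `zero_flag`).
#' @export
signConcordance <- function(pairs) {
    hasTm <- !is.na(pairs$thermo_tm) & !is.na(pairs$meso_tm)
    if (any(!hasTm)) {
        warning(sprintf("skipping %d pair(s) without Tm values",
                        sum(!hasTm)), call. = FALSE)
        pairs <- pairs[hasTm, , drop = FALSE]
    }
    dv <- pairs$meso_value - pairs$thermo_value
    dt <- pairs$meso_tm - pairs$thermo_tm
    zero <- dv == 0 | dt == 0
    conc <- !zero & sign(dv) == sign(dt)
    detail <- data.frame(
        protein = if ("protein" %in% names(pairs)) pairs$protein
                  else seq_along(dv),
        difference_value = dv, difference_tm = dt,
        concordant = conc, zero_flag = zero,
        stringsAsFactors = FALSE)
    list(nConcordant = sum(conc), nTotal = length(dv), detail = detail)
}
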