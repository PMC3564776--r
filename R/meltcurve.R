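# Boltzmann sigmoid fitting of thermal-shift fluorescence curves.

#' Boltzmann unfolding model
#'
#' \eqn{f(T) = f_{low} + (f_{high} - f_{low}) / (1 + \exp((T_m - T)/a))}.
#' At `t = tm` the model returns the midpoint `(fLow + fHigh) / 2`; for
#' `t` far below/above `tm` it approaches `fLow`/`fHigh`.
#'
#' @param t temperature(s) in degrees C.
#' @param tm melting temperature (transition midpoint), degrees C.
#' @param slopeA transition slope parameter, degrees C; must be non-zero.
#' @param fLow,fHigh folded / unfolded baseline fluorescence.
#' @return model fluorescence at `t`.
#' @examples
#' boltzmannModel(46, tm = 45, slopeA = 1, fLow = 0, fHigh = 100)
#' @export
boltzmannModel <- function(t, tm, slopeA, fLow, fHigh) {
    if (any(slopeA == 0)) stopf("slopeA must be non-zero")
    fLow + (fHigh - fLow) / (1 + exp((tm - t) / slopeA))
}

.movingAverage <- function(x, window = 5L) {
    as.numeric(stats::filter(x, rep(1 / window, window), sides = 2)) -> sm
    sm[is.na(sm)] <- x[is.na(sm)]
    sm
}

#' Fit a Boltzmann sigmoid to a melt curve
#'
#' Nonlinear least squares on [boltzmannModel()]. The fitted region runs
#' from the global minimum to the global maximum of a lightly smoothed
#' copy of the curve (centred moving average, window 5), excluding the
#' post-peak aggregation decay common in dye-based thermal-shift data.
#' Initialisation: baselines from the 5th/95th fluorescence percentiles
#' of the region, `tm` at the temperature of maximal finite-difference
#' slope, slope 1 degC. If the optimizer fails to converge, up to three
#' deterministic restarts perturb the starting `tm` by +5 and -5 degC
#' (fixed order, no randomness). Smoothing affects initialisation and
#' region selection only, never the fitted objective.
#'
#' @param curve a [MeltCurve-class] object.
#' @param smoothWindow moving-average window (points) for region
#'   selection and initialisation.
#' @return a [BoltzmannFit-class] object. A warning is issued (and the
#'   `reliable` flag cleared) when the fitted Tm falls outside the
#'   observed temperature range.
#' @export
fitTm <- function(curve, smoothWindow = 5L) {
    stopifnot(methods::is(curve, "MeltCurve"))
    t <- curveTemperatures(curve)
    f <- curveFluorescence(curve)
    sm <- .movingAverage(f, smoothWindow)
    rng <- max(sm) - min(sm)
    if (rng <= 0 || rng < 1e-12 * max(abs(sm), 1))
        stopf("no transition: curve is flat")
    iMin <- which.min(sm)
    iMax <- which.max(sm)
    if (iMax <= iMin)
        stopf("no transition: fluorescence maximum precedes the minimum")
    idx <- iMin:iMax
    if (length(idx) < 5L) stopf("no transition: rising region too short")
    tr <- t[idx]; fr <- f[idx]

    fLow0 <- stats::quantile(fr, 0.05, names = FALSE)
    fHigh0 <- stats::quantile(fr, 0.95, names = FALSE)
    slopes <- diff(sm[idx]) / diff(tr)
    tm0 <- tr[which.max(slopes)]
    tryFit <- function(tmStart) {
        fit <- try(minpack.lm::nlsLM(
            fr ~ fLow + (fHigh - fLow) / (1 + exp((tm - tr) / a)),
            start = list(fLow = fLow0, fHigh = fHigh0, tm = tmStart, a = 1),
            control = minpack.lm::nls.lm.control(
                maxiter = 200, ftol = 1e-8, ptol = 1e-8)),
            silent = TRUE)
        if (inherits(fit, "try-error")) return(NULL)
        fit
    }
    best <- NULL
    for (off in c(0, 5, -5)) {
        fit <- tryFit(tm0 + off)
        if (is.null(fit)) next
        conv <- fit$convInfo$isConv
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || (conv && !best$conv) ||
            (conv == best$conv && rss < best$rss))
            best <- list(fit = fit, conv = conv, rss = rss)
        if (!is.null(best) && best$conv) break
    }
    if (is.null(best)) stopf("Boltzmann fit failed for well '%s'",
                             wellId(curve))
    p <- stats::coef(best$fit)
    reliable <- p[["tm"]] >= min(t) && p[["tm"]] <= max(t)
    if (!reliable)
        warning(sprintf("unreliable fit: Tm %.2f outside data range [%g, %g]",
                        p[["tm"]], min(t), max(t)), call. = FALSE)
    new("BoltzmannFit", tm = unname(p[["tm"]]), slopeA = unname(p[["a"]]),
        fLow = unname(p[["fLow"]]), fHigh = unname(p[["fHigh"]]),
        rss = best$rss, converged = best$conv, reliable = reliable)
}

#' Fit every well of a melt plate
#'
#' @param curves list of [MeltCurve-class] objects (see
#'   [readMeltPlate()]).
#' @return data.frame with one row per well: `well_id`, `tm`, `slope_a`,
#'   `f_low`, `f_high`, `rss`, `converged`, `reliable`.
#' @export
fitPlate <- function(curves) {
    rows <- lapply(curves, function(cv) {
        fit <- fitTm(cv)
        data.frame(well_id = wellId(cv), tm = fit@tm, slope_a = fit@slopeA,
                   f_low = fit@fLow, f_high = fit@fHigh, rss = fit@rss,
                   converged = fit@converged, reliable = fit@reliable,
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
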