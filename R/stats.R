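#' Construct a GaussianFit
#'
#' Direct constructor, mainly for working with published fit parameters
#' (e.g. computing the 95\% bound implied by a reported center and
#' width). Uncertainties default to \code{NA}.
#'
#' @param center Gaussian center, nm.
#' @param width 1/e half-width w (> 0), nm; the standard deviation is
#'   \eqn{w/\sqrt{2}}.
#' @param centerSd,widthSd parameter SDs.
#' @param amplitude fitted amplitude.
#' @param binWidth histogram bin width, nm.
#' @param nPoints number of observations.
#' @return a [GaussianFit-class].
#' @export
GaussianFit <- function(center, width, centerSd = NA_real_,
                        widthSd = NA_real_, amplitude = NA_real_,
                        binWidth = NA_real_, nPoints = NA_integer_) {
    new("GaussianFit", center = as.numeric(center),
        centerSd = as.numeric(centerSd), width = as.numeric(width),
        widthSd = as.numeric(widthSd), amplitude = as.numeric(amplitude),
        binWidth = as.numeric(binWidth), nPoints = as.integer(nPoints))
}

#' @rdname accessors
setMethod("fitCenter", "GaussianFit", function(x) x@center)
#' @rdname accessors
setMethod("fitWidth", "GaussianFit", function(x) x@width)
#' @rdname accessors
setMethod("fitCenterSd", "GaussianFit", function(x) x@centerSd)
#' @rdname accessors
setMethod("fitWidthSd", "GaussianFit", function(x) x@widthSd)

setMethod("show", "GaussianFit", function(object) {
    cat(sprintf("GaussianFit: center = %.2f +/- %.2f nm, w = %.2f +/- %.2f nm\n",
                object@center, object@centerSd, object@width, object@widthSd))
    cat(sprintf("  (sigma = w/sqrt(2) = %.2f nm; bin width %g nm, n = %d)\n",
                object@width / sqrt(2), object@binWidth, object@nPoints))
})

## histogram of values at fixed bin width, bins aligned to multiples of bw
.clHistogram <- function(values, binWidth) {
    lo <- floor(min(values) / binWidth) * binWidth
    hi <- ceiling(max(values) / binWidth) * binWidth
    if (hi <= lo) hi <- lo + binWidth
    breaks <- seq(lo, hi, by = binWidth)
    hh <- graphics::hist(values, breaks = breaks, plot = FALSE)
    list(mids = hh$mids, counts = hh$counts)
}

#' Fit a Gaussian to a contour-length histogram
#'
#' Bins the values at a fixed bin width and least-squares fits
#' \eqn{A e^{-(x - c)^2 / w^2}} to the bin centers and counts. The
#' width parameter w is the 1/e half-width (\eqn{w = \sqrt{2}\sigma}).
#' Starting values are moment-based (sample mean, \eqn{\sqrt{2} \times}
#' sample SD, max count); parameter SDs come from the fit covariance.
#'
#' @param values numeric vector of contour lengths (>= 10 values).
#' @param binWidth histogram bin width in nm (default 2, matching the
#'   granularity of the published histograms).
#' @return a [GaussianFit-class].
#' @export
fitGaussianCL <- function(values, binWidth = 2) {
    values <- as.numeric(values)
    if (length(values) < 10L)
        stop("need at least 10 values for a histogram fit, got ",
             length(values))
    if (binWidth <= 0) stop("binWidth must be positive")
    if (stats::sd(values) == 0)
        stop("degenerate input: all ", length(values), " values equal ",
             values[1], "; a Gaussian width cannot be fitted")
    hh <- .clHistogram(values, binWidth)
    co <- .fitGaussianXY(hh$mids, hh$counts,
                         start = list(A = max(hh$counts), c = mean(values),
                                      w = sqrt(2) * stats::sd(values)),
                         binWidth = binWidth)
    GaussianFit(center = co["c", "Estimate"], width = abs(co["w", "Estimate"]),
                centerSd = co["c", "Std. Error"],
                widthSd = co["w", "Std. Error"],
                amplitude = co["A", "Estimate"], binWidth = binWidth,
                nPoints = length(values))
}

## least-squares Gaussian on (x, y) points; returns the coefficient table
.fitGaussianXY <- function(x, y, start, binWidth = NA) {
    df <- data.frame(x = x, y = y)
    fit <- tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-((x - c)^2) / w^2), data = df,
                          start = start,
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e)
            stop("Gaussian histogram fit did not converge (",
                 conditionMessage(e), "); starts were A=",
                 signif(start$A, 4), ", c=", signif(start$c, 4), ", w=",
                 signif(start$w, 4), " on ", nrow(df), " bins of width ",
                 binWidth))
    summary(fit)$coefficients
}

#' @rdname upperBound95
setMethod("upperBound95", "GaussianFit", function(fit, convention = c("sqrt2w", "sigma1.645")) {
    convention <- match.arg(convention)
    switch(convention,
           sqrt2w = fit@center + sqrt(2) * fit@width,
           sigma1.645 = fit@center + stats::qnorm(0.95) * fit@width)
})

#' Scale a random-control width to the native distribution
#'
#' Rescales the fitted width of the random-control distribution by the
#' ratio of the native to random centers (and an optional GC-content
#' factor) so that native and control widths are compared on a common
#' footing. Uncertainty is propagated in quadrature from the relative
#' uncertainties of the inputs.
#'
#' @param wRandom random-control width w, nm.
#' @param centerNative,centerRandom fitted centers, nm.
#' @param gcFactor additional dimensionless scaling (default 1).
#' @param wRandomSd,centerNativeSd,centerRandomSd input SDs (default 0).
#' @return list with elements \code{width} (nm) and \code{sd} (nm).
#' @examples
#' scaleWidth(2.6, 9.0, 7.7)$width  # 3.04 nm
#' @export
scaleWidth <- function(wRandom, centerNative, centerRandom, gcFactor = 1,
                       wRandomSd = 0, centerNativeSd = 0, centerRandomSd = 0) {
    if (wRandom <= 0 || centerNative <= 0 || gcFactor <= 0)
        stop("widths, centers and gcFactor must be positive")
    if (centerRandom <= 0)
        stop("centerRandom must be positive (division by its value)")
    w <- wRandom * (centerNative / centerRandom) * gcFactor
    rel <- sqrt((wRandomSd / wRandom)^2 + (centerNativeSd / centerNative)^2 +
                (centerRandomSd / centerRandom)^2)
    list(width = w, sd = w * rel)
}

#' Sigma-confidence of a width excess
#'
#' Number of standard deviations by which the native width exceeds the
#' scaled random-control width: \eqn{(w_{native} - w_{scaled}) /
#' SD(w_{scaled})}.
#'
#' @param wNative native width, nm.
#' @param wScaled scaled random-control width, nm.
#' @param wScaledSd its SD (> 0), nm.
#' @return numeric(1), the excess in sigma.
#' @examples
#' sigmaConfidence(6.03, 3.03, 0.81)  # 3.7
#' @export
sigmaConfidence <- function(wNative, wScaled, wScaledSd) {
    if (wScaledSd <= 0) stop("wScaledSd must be positive")
    (wNative - wScaled) / wScaledSd
}

#' Welch's unequal-variance t test (two-tailed)
#'
#' @param x,y numeric samples, each with >= 2 values and nonzero
#'   variance.
#' @return list with \code{t} (statistic), \code{dof}
#'   (Welch-Satterthwaite degrees of freedom) and \code{pValue}
#'   (two-tailed).
#' @export
welchTest <- function(x, y) {
    if (length(x) < 2L || length(y) < 2L)
        stop("each sample needs at least 2 values")
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
        stop("each sample must have nonzero variance")
    ht <- stats::t.test(x, y, var.equal = FALSE, alternative = "two.sided")
    list(t = unname(ht$statistic), dof = unname(ht$parameter),
         pValue = ht$p.value)
}

#' Standard error of the mean
#'
#' Sample standard deviation (n - 1 denominator) divided by
#' \eqn{\sqrt{n}}.
#'
#' @param values numeric sample with n >= 2.
#' @return numeric(1).
#' @export
sem <- function(values) {
    n <- length(values)
    if (n < 2L) stop("SEM needs at least 2 values")
    stats::sd(values) / sqrt(n)
}

#' Pearson correlation with ordinary least-squares fit
#'
#' Fits \eqn{y = a + bx} by OLS, computes the Pearson correlation
#' coefficient with its two-tailed p-value (t transform on n - 2
#' degrees of freedom), and retains the model for 95\% confidence-band
#' evaluation via [confidenceBand()].
#'
#' @param x predictor (e.g. GC\% or 3'UTR length in nt).
#' @param y response (contour length, nm).
#' @return a [LinearFit-class].
#' @export
pearsonLinfit <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    keep <- is.finite(x) & is.finite(y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L)
        stop("need at least 3 complete (x, y) pairs")
    if (stats::sd(x) == 0)
        stop("degenerate predictor: x has zero variance")
    if (stats::sd(y) == 0)
        stop("degenerate response: y has zero variance, r is undefined")
    model <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
    co <- summary(model)$coefficients
    ct <- stats::cor.test(x, y, method = "pearson",
                          alternative = "two.sided")
    new("LinearFit",
        intercept = co[1, 1], interceptSd = co[1, 2],
        slope = co[2, 1], slopeSd = co[2, 2],
        pearsonR = unname(ct$estimate), pValue = ct$p.value,
        df = as.integer(unname(ct$parameter)), model = model)
}

#' @rdname confidenceBand
setMethod("confidenceBand", "LinearFit", function(fit, x) {
    pr <- stats::predict(fit@model, newdata = data.frame(x = x),
                         interval = "confidence", level = 0.95)
    data.frame(x = x, fit = pr[, "fit"], lwr = pr[, "lwr"],
               upr = pr[, "upr"])
})

setMethod("show", "LinearFit", function(object) {
    cat(sprintf("LinearFit: y = a + bx, a = %.3g +/- %.2g, b = %.3g +/- %.2g\n",
                object@intercept, object@interceptSd, object@slope,
                object@slopeSd))
    cat(sprintf("  Pearson r(%d) = %.3f, two-tailed P = %.3g\n",
                object@df, object@pearsonR, object@pValue))
})
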