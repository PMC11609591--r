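#' Accessor generics
#'
#' Accessors for the classes in this package: record annotation slots,
#' structure pairing table and provenance, exterior-loop counts, and
#' Gaussian/linear fit parameters.
#'
#' @param x an object of the documented class.
#' @param ... passed to methods.
#' @return The slot value; see the class documentation for units.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seqId", function(x) standardGeneric("seqId"))

#' @rdname accessors
#' @export
setGeneric("speciesCode", function(x) standardGeneric("speciesCode"))

#' @rdname accessors
#' @export
setGeneric("clade", function(x) standardGeneric("clade"))

#' @rdname accessors
#' @export
setGeneric("geneClass", function(x) standardGeneric("geneClass"))

#' @rdname accessors
#' @export
setGeneric("rnaSequence", function(x) standardGeneric("rnaSequence"))

#' @rdname accessors
#' @export
setGeneric("utr5Span", function(x) standardGeneric("utr5Span"))

#' @rdname accessors
#' @export
setGeneric("cdsSpan", function(x) standardGeneric("cdsSpan"))

#' @rdname accessors
#' @export
setGeneric("utr3Span", function(x) standardGeneric("utr3Span"))

#' @rdname accessors
#' @export
setGeneric("pairTable", function(x) standardGeneric("pairTable"))

#' @rdname accessors
#' @export
setGeneric("freeEnergy", function(x) standardGeneric("freeEnergy"))

#' @rdname accessors
#' @export
setGeneric("engineInfo", function(x) standardGeneric("engineInfo"))

#' @rdname accessors
#' @export
setGeneric("dotBracket", function(x) standardGeneric("dotBracket"))

#' @rdname accessors
#' @export
setGeneric("extUnpaired", function(x) standardGeneric("extUnpaired"))

#' @rdname accessors
#' @export
setGeneric("topHelices", function(x) standardGeneric("topHelices"))

#' @rdname accessors
#' @export
setGeneric("linkCount", function(x) standardGeneric("linkCount"))

#' Contour length in nanometres
#'
#' Converts an exterior-loop link count to a contour length
#' \eqn{C_L = L \times d} with \eqn{d = 0.59} nm per link by default, or
#' extracts the stored contour length from an [ExteriorLoopSummary-class].
#'
#' @param x an \code{ExteriorLoopSummary}, or a non-negative numeric
#'   vector of link counts.
#' @param d nm per link (positive; default 0.59).
#' @return numeric, contour length(s) in nm.
#' @examples
#' contourLength(1)            # 0.59 nm, the smallest one-link loop
#' contourLength(13)           # 7.67 nm
#' @export
setGeneric("contourLength", function(x, d = 0.59) standardGeneric("contourLength"))

#' @rdname accessors
#' @export
setGeneric("fitCenter", function(x) standardGeneric("fitCenter"))

#' @rdname accessors
#' @export
setGeneric("fitWidth", function(x) standardGeneric("fitWidth"))

#' @rdname accessors
#' @export
setGeneric("fitCenterSd", function(x) standardGeneric("fitCenterSd"))

#' @rdname accessors
#' @export
setGeneric("fitWidthSd", function(x) standardGeneric("fitWidthSd"))

#' One-sided 95\% upper bound of a Gaussian contour-length distribution
#'
#' Under the 1/e half-width convention (\eqn{w = \sqrt{2}\sigma}) the
#' 95\% upper bound is \eqn{center + \sqrt{2} w} (equivalently
#' \eqn{\mu + 2\sigma}). An alternative convention treating the width
#' parameter as \eqn{\sigma} with a one-sided Gaussian quantile bound
#' \eqn{\mu + 1.645\sigma} is selectable but does not reproduce the
#' published bounds.
#'
#' @param fit a [GaussianFit-class].
#' @param convention \code{"sqrt2w"} (default) or \code{"sigma1.645"}.
#' @return numeric(1), the bound in nm.
#' @examples
#' upperBound95(GaussianFit(center = 9.0, width = 6.03))  # 17.53 nm
#' upperBound95(GaussianFit(center = 7.7, width = 2.6))   # 11.38 nm
#' @export
setGeneric("upperBound95",
    function(fit, convention = c("sqrt2w", "sigma1.645"))
        standardGeneric("upperBound95"))

#' 95\% confidence band of a linear fit
#'
#' Evaluates the 95\% confidence band for the mean response of a
#' [LinearFit-class] at new predictor values.
#'
#' @param fit a \code{LinearFit}.
#' @param x numeric vector of predictor values.
#' @return data.frame with columns \code{x}, \code{fit}, \code{lwr},
#'   \code{upr}.
#' @export
setGeneric("confidenceBand", function(fit, x) standardGeneric("confidenceBand"))
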