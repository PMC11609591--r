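#' @import methods
NULL

RNA_ALPHABET <- c("A", "C", "G", "U")
CLADE_LEVELS <- c("halobacteria", "viridiplantae", "invertebrate",
                  "vertebrate", "other")
GENE_CLASS_LEVELS <- c("homologous", "housekeeping", "highly_expressed",
                       "heterologous", "unknown")

## span slots hold integer(0) (absent) or a 1-based closed interval c(start, end)
.validSpan <- function(span, what) {
    if (length(span) == 0L)
        return(NULL)
    if (length(span) != 2L || anyNA(span))
        return(sprintf("%s span must be integer(0) or c(start, end)", what))
    if (span[1L] < 1L || span[2L] < span[1L])
        return(sprintf("%s span must satisfy 1 <= start <= end", what))
    NULL
}

#' MRNARecord: one mRNA sequence with annotations
#'
#' Container for a single sense-strand mRNA: identifier, species code
#' (e.g. \code{"GB"}, \code{"CR"}), clade and gene-class labels, the RNA
#' sequence (DNA input is normalized to RNA on construction), optional
#' 1-based closed UTR/CDS spans and a free-text provenance field.
#'
#' @slot id character(1) record identifier.
#' @slot speciesCode character(1) short species code.
#' @slot clade character(1), one of halobacteria, viridiplantae,
#'   invertebrate, vertebrate, other.
#' @slot geneClass character(1), one of homologous, housekeeping,
#'   highly_expressed, heterologous, unknown.
#' @slot sequence character(1) RNA string over A, C, G, U.
#' @slot utr5,cds,utr3 integer(0) when absent, else \code{c(start, end)},
#'   1-based closed coordinates on \code{sequence}.
#' @slot source character(1) provenance (file, database, "synthetic", ...).
#'
#' @seealso [mrnaRecord()] for the user constructor, [readSequences()].
#' @exportClass MRNARecord
setClass("MRNARecord",
    representation(id = "character", speciesCode = "character",
                   clade = "character", geneClass = "character",
                   sequence = "character",
                   utr5 = "integer", cds = "integer", utr3 = "integer",
                   source = "character"),
    prototype(speciesCode = NA_character_, clade = "other",
              geneClass = "unknown", utr5 = integer(0), cds = integer(0),
              utr3 = integer(0), source = ""))

setValidity("MRNARecord", function(object) {
    msg <- character(0)
    if (length(object@sequence) != 1L || nchar(object@sequence) < 1L)
        msg <- c(msg, "sequence must be a single non-empty string")
    else if (grepl(sprintf("[^%s]", paste(RNA_ALPHABET, collapse = "")),
                   object@sequence))
        msg <- c(msg, "sequence contains characters outside {A,C,G,U}")
    if (!object@clade %in% CLADE_LEVELS)
        msg <- c(msg, sprintf("clade must be one of: %s",
                              paste(CLADE_LEVELS, collapse = ", ")))
    if (!object@geneClass %in% GENE_CLASS_LEVELS)
        msg <- c(msg, sprintf("geneClass must be one of: %s",
                              paste(GENE_CLASS_LEVELS, collapse = ", ")))
    for (w in c("utr5", "cds", "utr3")) {
        bad <- .validSpan(slot(object, w), w)
        if (!is.null(bad)) msg <- c(msg, bad)
    }
    n <- if (length(object@sequence) == 1L) nchar(object@sequence) else 0L
    spans <- Filter(function(s) length(s) == 2L,
                    list(object@utr5, object@cds, object@utr3))
    for (s in spans)
        if (s[2L] > n)
            msg <- c(msg, "span extends beyond sequence end")
    ## when all three are present they must be ordered, non-overlapping
    if (length(object@utr5) == 2L && length(object@cds) == 2L &&
        length(object@utr3) == 2L) {
        if (!(object@utr5[2L] < object@cds[1L] &&
              object@cds[2L] < object@utr3[1L]))
            msg <- c(msg, "spans must be ordered utr5 < cds < utr3 without overlap")
    }
    if (length(msg)) msg else TRUE
})

#' SecondaryStructure: sequence plus base-pairing table
#'
#' A pseudoknot-free RNA secondary structure: the sequence, a pairing
#' table \code{pairs} with \code{pairs[i]} the 1-based partner of
#' position \code{i} (0 when unpaired), the predicted free energy in
#' kcal/mol when known, and the engine provenance string.
#'
#' Validity enforces the involution (\code{pairs[pairs[i]] == i}), bans
#' self-pairing and rejects crossing (pseudoknotted) pairs.
#'
#' @slot sequence character(1) RNA string.
#' @slot pairs integer vector, same length as the sequence.
#' @slot freeEnergy numeric(1) kcal/mol, \code{NA} when unknown.
#' @slot engine character(1) provenance (program, version, temperature).
#'
#' @seealso [foldMFE()], [parseDotBracket()], [parseCT()],
#'   [exteriorSummary()].
#' @exportClass SecondaryStructure
setClass("SecondaryStructure",
    representation(sequence = "character", pairs = "integer",
                   freeEnergy = "numeric", engine = "character"),
    prototype(freeEnergy = NA_real_, engine = "unknown"))

.checkNonCrossing <- function(pairs) {
    ## stack scan: an opening partner must close in LIFO order
    stack <- integer(0)
    for (i in seq_along(pairs)) {
        j <- pairs[i]
        if (j == 0L) next
        if (j > i) {
            stack <- c(stack, j)
        } else {
            if (length(stack) == 0L || stack[length(stack)] != i)
                return(FALSE)
            stack <- stack[-length(stack)]
        }
    }
    length(stack) == 0L
}

setValidity("SecondaryStructure", function(object) {
    msg <- character(0)
    n <- nchar(object@sequence)
    p <- object@pairs
    if (length(object@sequence) != 1L || n < 1L)
        msg <- c(msg, "sequence must be a single non-empty string")
    if (length(p) != n)
        return(c(msg, "pairs must have one entry per nucleotide"))
    if (anyNA(p) || any(p < 0L) || any(p > n))
        return(c(msg, "pairs entries must lie in 0..n"))
    paired <- which(p != 0L)
    if (any(p[paired] == paired))
        msg <- c(msg, "a position cannot pair with itself")
    if (!all(p[p[paired]] == paired))
        msg <- c(msg, "pairing is not an involution (pairs[pairs[i]] != i)")
    else if (!.checkNonCrossing(p))
        msg <- c(msg, "crossing base pairs (pseudoknot) are not supported")
    if (length(msg)) msg else TRUE
})

#' ExteriorLoopSummary: the exterior-loop statistic of one structure
#'
#' Result of [exteriorSummary()]: the number of depth-0 unpaired
#' nucleotides \code{u}, the number of depth-0 (outermost) helices
#' \code{h}, the number of links \code{L} along the exterior loop, and
#' the contour length \code{C_L = L * d} in nanometres.
#'
#' @slot extUnpaired integer(1) depth-0 unpaired nucleotide count (u).
#' @slot topHelices integer(1) depth-0 helix count (h).
#' @slot linkCount integer(1) exterior-loop link count (L).
#' @slot contourLength numeric(1) C_L in nm.
#' @slot convention character(1) link-counting convention used.
#' @slot d numeric(1) nm per link (default 0.59).
#'
#' @exportClass ExteriorLoopSummary
setClass("ExteriorLoopSummary",
    representation(extUnpaired = "integer", topHelices = "integer",
                   linkCount = "integer", contourLength = "numeric",
                   convention = "character", d = "numeric"))

setValidity("ExteriorLoopSummary", function(object) {
    msg <- character(0)
    if (object@extUnpaired < 0L || object@topHelices < 0L)
        msg <- c(msg, "counts must be non-negative")
    if (object@linkCount < 0L)
        msg <- c(msg, "linkCount must be non-negative")
    if (object@d <= 0)
        msg <- c(msg, "d must be positive")
    if (length(msg)) msg else TRUE
})

#' GaussianFit: Gaussian histogram fit with 1/e half-width convention
#'
#' Parameters of the least-squares fit of \eqn{A e^{-(x-c)^2/w^2}} to a
#' binned contour-length histogram. \code{width} is the 1/e half-width
#' \eqn{w}, related to the standard deviation by \eqn{w = \sqrt{2}\sigma}.
#' Parameter uncertainties come from the fit covariance; they are
#' \code{NA} for fits constructed directly from literature values.
#'
#' @slot center,centerSd numeric(1) fitted center (nm) and its SD.
#' @slot width,widthSd numeric(1) fitted 1/e half-width w (nm) and its SD.
#' @slot amplitude numeric(1) fitted amplitude (counts).
#' @slot binWidth numeric(1) histogram bin width used (nm).
#' @slot nPoints integer(1) number of observations behind the histogram.
#'
#' @seealso [fitGaussianCL()], [upperBound95()], [GaussianFit()].
#' @exportClass GaussianFit
setClass("GaussianFit",
    representation(center = "numeric", centerSd = "numeric",
                   width = "numeric", widthSd = "numeric",
                   amplitude = "numeric", binWidth = "numeric",
                   nPoints = "integer"),
    prototype(centerSd = NA_real_, widthSd = NA_real_,
              amplitude = NA_real_, binWidth = NA_real_, nPoints = NA_integer_))

setValidity("GaussianFit", function(object) {
    if (!is.finite(object@width) || object@width <= 0)
        "width (1/e half-width) must be positive"
    else TRUE
})

#' LinearFit: OLS fit with Pearson correlation and confidence band
#'
#' Result of [pearsonLinfit()]: intercept and slope of \eqn{y = a + bx}
#' with standard errors, the Pearson correlation coefficient with its
#' two-tailed p-value, and the fitted \code{lm} object from which the
#' 95\% confidence band for the mean response is evaluated via
#' [confidenceBand()].
#'
#' @slot intercept,interceptSd numeric(1) a and SE(a).
#' @slot slope,slopeSd numeric(1) b and SE(b).
#' @slot pearsonR numeric(1) Pearson r.
#' @slot pValue numeric(1) two-tailed p for r.
#' @slot df integer(1) residual degrees of freedom (n - 2).
#' @slot model the underlying \code{lm} fit.
#'
#' @exportClass LinearFit
setClass("LinearFit",
    representation(intercept = "numeric", interceptSd = "numeric",
                   slope = "numeric", slopeSd = "numeric",
                   pearsonR = "numeric", pValue = "numeric",
                   df = "integer", model = "ANY"))

setValidity("LinearFit", function(object) {
    msg <- character(0)
    if (abs(object@pearsonR) > 1 + 1e-12)
        msg <- c(msg, "pearsonR must lie in [-1, 1]")
    if (object@pValue < 0 || object@pValue > 1)
        msg <- c(msg, "pValue must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' SurveyReport: end-to-end contour-length survey results
#'
#' Output of [runSurvey()]: the per-molecule table (id, species, clade,
#' gene class, length, GC\%, 3'UTR length, u, h, L, C_L), per-species
#' aggregates (mean C_L with SEM), the pooled Gaussian fit (or NULL when
#' too few molecules), labelled Welch comparisons and correlations, the
#' skipped-record table and engine provenance.
#'
#' @slot perMolecule data.frame, one row per measured molecule.
#' @slot perSpecies data.frame with columns speciesCode, n, meanCL, semCL.
#' @slot fit [GaussianFit-class] or NULL.
#' @slot comparisons named list of Welch test results.
#' @slot correlations named list of [LinearFit-class] results.
#' @slot skipped data.frame (id, reason) of records not measured.
#' @slot engine character(1) provenance.
#'
#' @exportClass SurveyReport
setClass("SurveyReport",
    representation(perMolecule = "data.frame", perSpecies = "data.frame",
                   fit = "ANY", comparisons = "list", correlations = "list",
                   skipped = "data.frame", engine = "character"))

setValidity("SurveyReport", function(object) {
    if (nrow(object@perSpecies) &&
        sum(object@perSpecies$n) != nrow(object@perMolecule))
        "perSpecies n values must sum to the perMolecule row count"
    else TRUE
})
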