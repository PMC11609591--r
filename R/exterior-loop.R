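#' Exterior-loop summary of a secondary structure
#'
#' Walks the backbone at nesting depth 0 and summarizes the exterior
#' loop — the path connecting the 5' and 3' termini. Exterior nodes are
#' the depth-0 unpaired nucleotides plus, for each outermost (depth-0)
#' helix, the two nucleotides of its closing base pair; consecutive
#' exterior nodes are joined by one link each (a backbone bond, or the
#' bridging base pair across a helix). Under this default convention
#' the link count is \eqn{L = u + 2h - 1} and the contour length is
#' \eqn{C_L = L \times d}.
#'
#' The smallest possible loop — both termini directly base-paired, u =
#' 0, h = 1 — has exactly one link, C_L = 0.59 nm with the default d.
#' A single-nucleotide structure has u = 1, h = 0, L = 0, C_L = 0.
#'
#' Two alternative conventions are selectable for comparison:
#' \code{"helixNode"} treats each depth-0 helix as a single zero-width
#' node (L = u + h - 1) and \code{"unpairedOnly"} counts only unpaired
#' exterior nucleotides (L = u).
#'
#' @param structure a [SecondaryStructure-class].
#' @param d nm per link; default 0.59, the typical inter-nucleotide
#'   distance in RNA.
#' @param convention link-counting convention (see Details).
#' @return an [ExteriorLoopSummary-class].
#' @examples
#' s <- parseDotBracket(c("AAGCAAAGCAA", "..((...)).."))
#' exteriorSummary(s)  # u=4, h=1, L=5, C_L=2.95 nm
#' @export
exteriorSummary <- function(structure, d = 0.59,
                            convention = c("bridged", "helixNode",
                                           "unpairedOnly")) {
    stopifnot(is(structure, "SecondaryStructure"))
    convention <- match.arg(convention)
    if (d <= 0) stop("d must be positive")
    p <- pairTable(structure)
    n <- length(p)
    if (n < 1L) stop("empty structure")
    u <- 0L; h <- 0L
    i <- 1L
    while (i <= n) {
        if (p[i] == 0L) {
            u <- u + 1L
            i <- i + 1L
        } else {
            ## depth-0 opening pair: its helix is one exterior unit;
            ## skip everything it encloses
            h <- h + 1L
            i <- p[i] + 1L
        }
    }
    L <- switch(convention,
                bridged = u + 2L * h - 1L,
                helixNode = u + h - 1L,
                unpairedOnly = u)
    L <- max(L, 0L)
    new("ExteriorLoopSummary", extUnpaired = u, topHelices = h,
        linkCount = L, contourLength = L * d, convention = convention, d = d)
}

#' @rdname accessors
setMethod("extUnpaired", "ExteriorLoopSummary", function(x) x@extUnpaired)
#' @rdname accessors
setMethod("topHelices", "ExteriorLoopSummary", function(x) x@topHelices)
#' @rdname accessors
setMethod("linkCount", "ExteriorLoopSummary", function(x) x@linkCount)

#' @rdname contourLength
setMethod("contourLength", "ExteriorLoopSummary",
    function(x, d = 0.59) x@contourLength)

#' @rdname contourLength
setMethod("contourLength", "numeric", function(x, d = 0.59) {
    if (any(x < 0)) stop("link counts must be non-negative")
    if (d <= 0) stop("d must be positive")
    x * d
})

setMethod("show", "ExteriorLoopSummary", function(object) {
    cat(sprintf(
        "ExteriorLoopSummary: u=%d unpaired, h=%d helices, L=%d links, C_L=%.2f nm (d=%g, %s)\n",
        object@extUnpaired, object@topHelices, object@linkCount,
        object@contourLength, object@d, object@convention))
})
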