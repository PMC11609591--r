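#' Run the end-to-end contour-length survey
#'
#' For each eligible record: (optionally) trims the terminal poly-A
#' run, folds to the MFE structure, summarizes the exterior loop and
#' records length, GC\% and 3'UTR length. Aggregates mean contour
#' length with SEM per species, fits the pooled histogram when at
#' least \code{minFit} molecules were measured, runs the configured
#' pairwise Welch comparisons and the GC / 3'UTR-length correlations.
#' Records that fail eligibility or folding are never silently
#' dropped: they appear in the skipped table with a reason.
#'
#' @param records list of [MRNARecord-class].
#' @param criteria eligibility [filterCriteria()].
#' @param engine folding [viennaEngine()].
#' @param d nm per exterior-loop link.
#' @param convention link-counting convention, see [exteriorSummary()].
#' @param binWidth histogram bin width for the pooled fit, nm.
#' @param trimPolyA trim the terminal poly-A run before folding
#'   (default TRUE; the tail cannot pair and would only lengthen the
#'   exterior loop).
#' @param comparisons named list of group contrasts, each
#'   \code{list(field =, a =, b =)} with \code{field} one of
#'   \code{"speciesCode"}, \code{"geneClass"}, \code{"clade"}; a Welch
#'   test of contour lengths between groups a and b is run per entry.
#' @param minFit minimum measured molecules for the pooled Gaussian fit.
#' @return a [SurveyReport-class].
#' @export
runSurvey <- function(records, criteria = filterCriteria(),
                      engine = viennaEngine(), d = 0.59,
                      convention = "bridged", binWidth = 2,
                      trimPolyA = TRUE, comparisons = list(),
                      minFit = 10L) {
    stopifnot(length(records) >= 1L)
    rows <- list(); skipped <- list()
    for (rec in records) {
        elig <- checkEligibility(rec, criteria)
        if (!elig$passed) {
            skipped[[length(skipped) + 1L]] <- data.frame(
                id = seqId(rec),
                reason = paste("ineligible:",
                               paste(elig$failures, collapse = ",")),
                stringsAsFactors = FALSE)
            next
        }
        seq <- rnaSequence(rec)
        if (trimPolyA) seq <- trimPolyATail(seq, criteria$minPolyARun)
        structure <- tryCatch(foldMFE(seq, engine), error = function(e) e)
        if (inherits(structure, "error")) {
            skipped[[length(skipped) + 1L]] <- data.frame(
                id = seqId(rec),
                reason = paste("folding failed:",
                               conditionMessage(structure)),
                stringsAsFactors = FALSE)
            next
        }
        es <- exteriorSummary(structure, d = d, convention = convention)
        rows[[length(rows) + 1L]] <- data.frame(
            id = seqId(rec), speciesCode = speciesCode(rec),
            clade = clade(rec), geneClass = geneClass(rec),
            length = nchar(rnaSequence(rec)),
            gc = gcContent(rnaSequence(rec)),
            utr3Length = utr3Length(rec),
            u = extUnpaired(es), h = topHelices(es), L = linkCount(es),
            CL = contourLength(es), stringsAsFactors = FALSE)
    }
    perMolecule <- if (length(rows)) do.call(rbind, rows) else
        data.frame(id = character(0), speciesCode = character(0),
                   clade = character(0), geneClass = character(0),
                   length = integer(0), gc = numeric(0),
                   utr3Length = integer(0), u = integer(0), h = integer(0),
                   L = integer(0), CL = numeric(0))
    skippedDf <- if (length(skipped)) do.call(rbind, skipped) else
        data.frame(id = character(0), reason = character(0))
    if (!nrow(perMolecule))
        stop("no record survived eligibility and folding; reasons: ",
             paste(unique(skippedDf$reason), collapse = "; "))

    perSpecies <- do.call(rbind, lapply(
        split(perMolecule, perMolecule$speciesCode), function(g)
            data.frame(speciesCode = g$speciesCode[1], n = nrow(g),
                       meanCL = mean(g$CL),
                       semCL = if (nrow(g) >= 2) sem(g$CL) else NA_real_,
                       stringsAsFactors = FALSE)))
    rownames(perSpecies) <- NULL

    fit <- if (nrow(perMolecule) >= minFit)
        tryCatch(fitGaussianCL(perMolecule$CL, binWidth = binWidth),
                 error = function(e) NULL)
    else NULL

    comps <- lapply(comparisons, function(cmp) {
        stopifnot(cmp$field %in% c("speciesCode", "geneClass", "clade"))
        a <- perMolecule$CL[perMolecule[[cmp$field]] == cmp$a]
        b <- perMolecule$CL[perMolecule[[cmp$field]] == cmp$b]
        if (length(a) < 2L || length(b) < 2L)
            return(list(t = NA_real_, dof = NA_real_, pValue = NA_real_,
                        note = "too few molecules in a group"))
        if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
            ## degenerate but unambiguous: identical groups do not differ
            return(list(t = 0, dof = NA_real_, pValue = 1,
                        nA = length(a), nB = length(b)))
        c(welchTest(a, b), list(nA = length(a), nB = length(b)))
    })

    corrs <- list()
    ok <- is.finite(perMolecule$gc)
    if (sum(ok) >= 3L && stats::sd(perMolecule$gc[ok]) > 0)
        corrs$gc <- pearsonLinfit(perMolecule$gc, perMolecule$CL)
    okU <- is.finite(perMolecule$utr3Length)
    if (sum(okU) >= 3L && stats::sd(perMolecule$utr3Length[okU]) > 0)
        corrs$utr3Length <- pearsonLinfit(perMolecule$utr3Length,
                                          perMolecule$CL)

    new("SurveyReport", perMolecule = perMolecule, perSpecies = perSpecies,
        fit = fit, comparisons = comps, correlations = corrs,
        skipped = skippedDf,
        engine = .engineProvenance(engine, "RNAfold"))
}

setMethod("show", "SurveyReport", function(object) {
    cat(sprintf("SurveyReport: %d molecules measured (%d skipped), %d species\n",
                nrow(object@perMolecule), nrow(object@skipped),
                nrow(object@perSpecies)))
    cat("  engine:", object@engine, "\n")
    if (!is.null(object@fit))
        cat(sprintf("  pooled fit: center %.2f nm, w %.2f nm, bound %.2f nm\n",
                    fitCenter(object@fit), fitWidth(object@fit),
                    upperBound95(object@fit)))
})

#' Random-sequence null model of the contour-length distribution
#'
#' Generates uniform-composition random sequences, folds each to its
#' MFE structure, measures the exterior-loop contour length, fits the
#' pooled histogram and returns the fit together with its 95\% upper
#' bound. Defaults regenerate the published control: 50 sequences of
#' 1600 nt with equal base probabilities.
#'
#' @param count,length,baseProbs,seed passed to
#'   [generateRandomSequences()].
#' @param engine folding [viennaEngine()].
#' @param d nm per link.
#' @param binWidth histogram bin width, nm.
#' @return list with \code{fit} ([GaussianFit-class]),
#'   \code{upperBound} (nm), \code{values} (per-sequence C_L, nm) and
#'   \code{seed}.
#' @export
runRandomControl <- function(count = 50L, length = 1600L,
                             baseProbs = rep(0.25, 4), seed = NULL,
                             engine = viennaEngine(), d = 0.59,
                             binWidth = 2) {
    if (count < 1L) stop("count must be >= 1: nothing to fold or fit")
    seqs <- generateRandomSequences(count, length, baseProbs, seed)
    values <- vapply(seqs, function(s)
        contourLength(exteriorSummary(foldMFE(s, engine), d = d)),
        numeric(1))
    fit <- fitGaussianCL(values, binWidth = binWidth)
    list(fit = fit, upperBound = upperBound95(fit), values = values,
         seed = seed)
}

#' Contour-length stability of MFE versus suboptimal structures
#'
#' For each sequence, folds the MFE structure and the \code{k}
#' lowest-energy suboptimal structures, computes the contour-length
#' ratio C_L(suboptimal) / C_L(MFE) per suboptimal, and Welch-tests
#' the MFE contour lengths against the pooled suboptimal contour
#' lengths (two-tailed). A sequence whose MFE contour length is zero
#' has undefined ratios; it is flagged and excluded.
#'
#' @param sequences character vector of RNA sequences (>= 2).
#' @param k suboptimal structures per sequence (beyond the MFE).
#' @param engine folding [viennaEngine()].
#' @param d nm per link.
#' @return list with \code{ratios} (data.frame: id, rank, energy,
#'   CL, ratio), \code{mfeCL} (named numeric), \code{welch}
#'   ([welchTest()] result) and \code{excluded} (character ids).
#' @export
compareMFESuboptimal <- function(sequences, k = 5L, engine = viennaEngine(),
                                 d = 0.59) {
    stopifnot(length(sequences) >= 2L)
    ids <- names(sequences)
    if (is.null(ids)) ids <- paste0("seq", seq_along(sequences))
    rows <- list(); mfeCL <- numeric(0); excluded <- character(0)
    for (i in seq_along(sequences)) {
        structs <- foldSuboptimal(sequences[[i]], k = k + 1L, engine = engine)
        cls <- vapply(structs, function(s)
            contourLength(exteriorSummary(s, d = d)), numeric(1))
        if (cls[1] == 0) {
            warning("sequence '", ids[i],
                    "' has zero MFE contour length; ratios undefined, excluded")
            excluded <- c(excluded, ids[i])
            next
        }
        mfeCL[ids[i]] <- cls[1]
        rows[[length(rows) + 1L]] <- data.frame(
            id = ids[i], rank = seq_len(k),
            energy = vapply(structs[-1], freeEnergy, numeric(1)),
            CL = cls[-1], ratio = cls[-1] / cls[1],
            stringsAsFactors = FALSE)
    }
    if (length(mfeCL) < 2L)
        stop("fewer than 2 sequences with a nonzero MFE contour length")
    ratios <- do.call(rbind, rows)
    welch <- welchTest(unname(mfeCL), ratios$CL)
    list(ratios = ratios, mfeCL = mfeCL, welch = welch, excluded = excluded)
}

## ---- serialization -------------------------------------------------------

#' Write a survey report to disk
#'
#' Emits \code{per_molecule.tsv}, \code{per_species.tsv},
#' \code{fits.json} (pooled fit parameters with uncertainties and the
#' 95\% bound) and \code{comparisons.json} (Welch comparisons and
#' correlation fits) into a directory.
#'
#' @param report a [SurveyReport-class].
#' @param dir output directory (created if missing).
#' @return (invisibly) the directory.
#' @export
writeSurveyReport <- function(report, dir) {
    stopifnot(is(report, "SurveyReport"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    num <- function(x) round(x, 6)
    utils::write.table(
        within(report@perMolecule, { gc <- num(gc); CL <- num(CL) }),
        file.path(dir, "per_molecule.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
        within(report@perSpecies,
               { meanCL <- num(meanCL); semCL <- num(semCL) }),
        file.path(dir, "per_species.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    fits <- list(engine = report@engine, n = nrow(report@perMolecule))
    if (!is.null(report@fit)) {
        f <- report@fit
        fits$gaussian <- list(center = fitCenter(f),
                              centerSd = fitCenterSd(f),
                              width = fitWidth(f), widthSd = fitWidthSd(f),
                              binWidth = f@binWidth,
                              upperBound95 = upperBound95(f))
    }
    jsonlite::write_json(fits, file.path(dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    lin <- function(lf) list(intercept = lf@intercept,
                             interceptSd = lf@interceptSd,
                             slope = lf@slope, slopeSd = lf@slopeSd,
                             pearsonR = lf@pearsonR, pValue = lf@pValue,
                             df = lf@df)
    jsonlite::write_json(
        list(comparisons = report@comparisons,
             correlations = lapply(report@correlations, lin)),
        file.path(dir, "comparisons.json"),
        auto_unbox = TRUE, digits = NA, null = "null")
    invisible(dir)
}
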