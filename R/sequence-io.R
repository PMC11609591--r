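#' Normalize a nucleotide string to the RNA alphabet
#'
#' Upper-cases and converts T to U. Any character outside {A,C,G,U}
#' after normalization is an error (IUPAC ambiguity codes are not
#' accepted: the downstream folding engines require unambiguous input).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector over {A,C,G,U}.
#' @export
normalizeRNA <- function(x) {
    out <- chartr("t", "u", tolower(x))
    out <- toupper(out)
    bad <- grepl("[^ACGU]", out)
    if (any(bad))
        stop("sequence contains non-ACGT/U characters: ",
             paste(unique(unlist(strsplit(gsub("[ACGU]", "", out[bad]), ""))),
                   collapse = ", "))
    out
}

#' Construct an MRNARecord
#'
#' @param id record identifier.
#' @param sequence nucleotide string (DNA accepted, normalized to RNA).
#' @param speciesCode short species code such as \code{"CR"} or
#'   \code{"GB"}; \code{NA} when unknown.
#' @param clade one of \code{"halobacteria"}, \code{"viridiplantae"},
#'   \code{"invertebrate"}, \code{"vertebrate"}, \code{"other"}.
#' @param geneClass one of \code{"homologous"}, \code{"housekeeping"},
#'   \code{"highly_expressed"}, \code{"heterologous"}, \code{"unknown"}.
#' @param utr5,cds,utr3 optional 1-based closed intervals
#'   \code{c(start, end)}; omit or pass \code{NULL} when unannotated.
#' @param source free-text provenance.
#' @return an [MRNARecord-class].
#' @examples
#' rec <- mrnaRecord("ex1", "ACGTACGT")   # DNA input is normalized
#' rnaSequence(rec)
#' @export
mrnaRecord <- function(id, sequence, speciesCode = NA_character_,
                       clade = "other", geneClass = "unknown",
                       utr5 = NULL, cds = NULL, utr3 = NULL, source = "") {
    asSpan <- function(s) if (is.null(s) || !length(s)) integer(0) else as.integer(s)
    new("MRNARecord", id = as.character(id),
        sequence = normalizeRNA(sequence),
        speciesCode = as.character(speciesCode), clade = clade,
        geneClass = geneClass, utr5 = asSpan(utr5), cds = asSpan(cds),
        utr3 = asSpan(utr3), source = source)
}

#' @rdname accessors
setMethod("seqId", "MRNARecord", function(x) x@id)
#' @rdname accessors
setMethod("speciesCode", "MRNARecord", function(x) x@speciesCode)
#' @rdname accessors
setMethod("clade", "MRNARecord", function(x) x@clade)
#' @rdname accessors
setMethod("geneClass", "MRNARecord", function(x) x@geneClass)
#' @rdname accessors
setMethod("rnaSequence", "MRNARecord", function(x) x@sequence)
#' @rdname accessors
setMethod("utr5Span", "MRNARecord", function(x) x@utr5)
#' @rdname accessors
setMethod("cdsSpan", "MRNARecord", function(x) x@cds)
#' @rdname accessors
setMethod("utr3Span", "MRNARecord", function(x) x@utr3)

setMethod("show", "MRNARecord", function(object) {
    fmtSpan <- function(s) if (length(s)) sprintf("%d..%d", s[1], s[2]) else "."
    cat(sprintf("MRNARecord %s: %d nt, species=%s, clade=%s, class=%s\n",
                object@id, nchar(object@sequence), object@speciesCode,
                object@clade, object@geneClass))
    cat(sprintf("  5'UTR %s | CDS %s | 3'UTR %s\n",
                fmtSpan(object@utr5), fmtSpan(object@cds), fmtSpan(object@utr3)))
})

## ---- readers -------------------------------------------------------------

#' Read mRNA sequences from FASTA or GenBank flat files
#'
#' FASTA entries become records with empty spans; GenBank records have
#' their 5'UTR, CDS and 3'UTR feature locations (simple \code{a..b}
#' locations) copied into the spans and the \code{/organism} qualifier
#' into the source field. DNA is normalized to RNA.
#'
#' @param path path to the input file.
#' @param format \code{"fasta"} or \code{"genbank"}.
#' @return list of [MRNARecord-class] objects.
#' @export
readSequences <- function(path, format = c("fasta", "genbank")) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("cannot read '", path, "': no such file")
    switch(format,
           fasta = .readFastaRecords(path),
           genbank = .readGenBankRecords(path))
}

.readFastaRecords <- function(path) {
    set <- tryCatch(Biostrings::readBStringSet(path),
                    error = function(e)
                        stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e)))
    ids <- sub("\\s.*$", "", names(set))
    lapply(seq_along(set), function(i) {
        tryCatch(mrnaRecord(ids[i], as.character(set[[i]]), source = path),
                 error = function(e)
                     stop("malformed FASTA entry '", ids[i], "': ",
                          conditionMessage(e)))
    })
}

## Minimal GenBank flat-file parser: LOCUS, FEATURES (5'UTR/CDS/3'UTR with
## simple a..b locations, /organism qualifier), ORIGIN sequence block.
.readGenBankRecords <- function(path) {
    lines <- readLines(path, warn = FALSE)
    if (!length(lines) || !any(grepl("^LOCUS", lines)))
        stop("'", path, "' does not look like a GenBank flat file (no LOCUS line)")
    starts <- grep("^LOCUS", lines)
    ends <- c(starts[-1] - 1L, length(lines))
    mapply(function(s, e) .parseGenBankEntry(lines[s:e], path),
           starts, ends, SIMPLIFY = FALSE)
}

.parseGenBankEntry <- function(entry, path) {
    locus <- strsplit(trimws(entry[1]), "\\s+")[[1]]
    id <- if (length(locus) >= 2) locus[2] else "unknown"
    acc <- grep("^ACCESSION", entry, value = TRUE)
    if (length(acc))
        id <- strsplit(trimws(acc[1]), "\\s+")[[1]][2]

    featLoc <- function(key) {
        ## feature keys start at column 6; location on the same line
        pat <- sprintf("^ {2,8}%s\\s+", gsub("'", "'", key, fixed = TRUE))
        hit <- grep(pat, entry)
        if (!length(hit)) return(integer(0))
        loc <- sub(pat, "", entry[hit[1]])
        if (grepl("complement|join|order", loc))
            stop("GenBank record '", id,
                 "': only simple a..b feature locations are supported, got: ",
                 trimws(loc))
        m <- regmatches(loc, regexec("([0-9]+)\\.\\.([0-9]+)", loc))[[1]]
        if (length(m) != 3)
            stop("GenBank record '", id, "': cannot parse ", key,
                 " location: ", trimws(loc))
        as.integer(m[2:3])
    }
    org <- grep("/organism=", entry, value = TRUE)
    organism <- if (length(org))
        sub('.*/organism="([^"]*)".*', "\\1", org[1]) else NA_character_

    oi <- grep("^ORIGIN", entry)
    if (!length(oi))
        stop("GenBank record '", id, "' has no ORIGIN block")
    ei <- grep("^//", entry)
    ei <- if (length(ei)) ei[1] - 1L else length(entry)
    seqLines <- entry[(oi[1] + 1L):ei]
    seq <- gsub("[0-9 /]", "", paste(seqLines, collapse = ""))
    if (!nchar(seq))
        stop("GenBank record '", id, "' has an empty ORIGIN block")
    src <- if (is.na(organism)) path else sprintf("%s (%s)", path, organism)
    tryCatch(
        mrnaRecord(id, seq, utr5 = featLoc("5'UTR"), cds = featLoc("CDS"),
                   utr3 = featLoc("3'UTR"), source = src),
        error = function(e)
            stop("malformed GenBank record '", id, "': ", conditionMessage(e)))
}

## ---- eligibility ---------------------------------------------------------

#' Eligibility criteria for full-length mRNA records
#'
#' The survey admits only full-length transcriptional units: both UTRs
#' annotated, a polyadenylation signal (PAS) plus the start of the
#' poly-A tail in the 3' region, and total length within a window.
#'
#' @param minLen,maxLen length window in nt (defaults 200 and 7000).
#' @param requireUTRs require both 5'UTR and 3'UTR annotations.
#' @param pasMotifs RNA hexamers accepted as PAS; defaults to the
#'   canonical AAUAAA plus the common variant AUUAAA. The set is an
#'   explicit configuration because PAS usage varies across species.
#' @param minPolyARun minimum number of consecutive A at (or running
#'   over) the 3' terminus accepted as the start of the poly-A tail.
#' @param checkPAS,checkPolyA toggles for the two 3'-end checks.
#' @return a \code{FilterCriteria} list.
#' @export
filterCriteria <- function(minLen = 200L, maxLen = 7000L, requireUTRs = TRUE,
                           pasMotifs = c("AAUAAA", "AUUAAA"),
                           minPolyARun = 8L, checkPAS = TRUE,
                           checkPolyA = TRUE) {
    stopifnot(minLen <= maxLen, minPolyARun >= 1L)
    if (checkPAS && !length(pasMotifs))
        stop("pasMotifs must be non-empty when the PAS check is enabled")
    structure(list(minLen = as.integer(minLen), maxLen = as.integer(maxLen),
                   requireUTRs = requireUTRs,
                   pasMotifs = normalizeRNA(pasMotifs),
                   minPolyARun = as.integer(minPolyARun),
                   checkPAS = checkPAS, checkPolyA = checkPolyA),
              class = "FilterCriteria")
}

## region searched for the PAS / poly-A start: the annotated 3'UTR when
## present, else the final 200 nt
.threePrimeRegion <- function(record, window = 200L) {
    n <- nchar(record@sequence)
    if (length(record@utr3) == 2L)
        substr(record@sequence, record@utr3[1], n)
    else
        substr(record@sequence, max(1L, n - window + 1L), n)
}

.hasTerminalPolyARun <- function(seq, minRun) {
    grepl(sprintf("A{%d,}$", minRun), seq)
}

#' Check a record against the eligibility criteria
#'
#' Evaluates every criterion and accumulates all failures rather than
#' short-circuiting. The PAS is searched within the annotated 3'UTR
#' when present, otherwise within the final 200 nt; the poly-A start is
#' a run of at least \code{minPolyARun} consecutive A ending at the 3'
#' terminus.
#'
#' @param record an [MRNARecord-class].
#' @param criteria a [filterCriteria()] list.
#' @return list with elements \code{passed} (logical) and
#'   \code{failures} (character vector of reason codes among TOO_SHORT,
#'   TOO_LONG, NO_UTR5, NO_UTR3, NO_PAS, NO_POLYA_START);
#'   \code{passed} is TRUE iff \code{failures} is empty.
#' @export
checkEligibility <- function(record, criteria = filterCriteria()) {
    stopifnot(is(record, "MRNARecord"), inherits(criteria, "FilterCriteria"))
    fails <- character(0)
    n <- nchar(record@sequence)
    if (n < criteria$minLen) fails <- c(fails, "TOO_SHORT")
    if (n > criteria$maxLen) fails <- c(fails, "TOO_LONG")
    if (criteria$requireUTRs) {
        if (length(record@utr5) != 2L) fails <- c(fails, "NO_UTR5")
        if (length(record@utr3) != 2L) fails <- c(fails, "NO_UTR3")
    }
    region <- .threePrimeRegion(record)
    if (criteria$checkPAS &&
        !any(vapply(criteria$pasMotifs, grepl, logical(1), x = region,
                    fixed = TRUE)))
        fails <- c(fails, "NO_PAS")
    if (criteria$checkPolyA &&
        !.hasTerminalPolyARun(record@sequence, criteria$minPolyARun))
        fails <- c(fails, "NO_POLYA_START")
    list(passed = length(fails) == 0L, failures = fails)
}

#' Trim the terminal poly-A run before folding
#'
#' A long homopolymer tail cannot base-pair internally and would
#' trivially inflate the exterior loop, so by default the survey folds
#' each molecule up to and including the PAS-bearing 3'UTR but without
#' the poly-A tail. Runs shorter than \code{minRun} are left in place.
#'
#' @param sequence RNA string.
#' @param minRun minimum terminal A-run length treated as a tail.
#' @return the sequence with any terminal run of >= \code{minRun} A
#'   removed.
#' @export
trimPolyATail <- function(sequence, minRun = 8L) {
    sub(sprintf("A{%d,}$", as.integer(minRun)), "", sequence)
}

#' GC content of a sequence, in percent
#'
#' @param sequence character vector of non-empty RNA/DNA strings.
#' @return numeric, \code{100 * (\#G + \#C) / length} per sequence.
#' @examples
#' gcContent("GCAU")  # 50
#' @export
gcContent <- function(sequence) {
    if (any(!nzchar(sequence)))
        stop("gcContent is undefined for an empty sequence")
    vapply(sequence, function(s) {
        n <- nchar(s)
        100 * (n - nchar(gsub("[GCgc]", "", s))) / n
    }, numeric(1), USE.NAMES = FALSE)
}

#' 3'UTR length of a record, in nt
#'
#' Width of the 1-based closed 3'UTR interval (\code{end - start + 1}),
#' or \code{NA} when the record carries no 3'UTR annotation (such
#' records are excluded from length correlations downstream).
#'
#' @param record an [MRNARecord-class].
#' @return integer(1) or \code{NA}.
#' @export
utr3Length <- function(record) {
    stopifnot(is(record, "MRNARecord"))
    if (length(record@utr3) != 2L) return(NA_integer_)
    record@utr3[2L] - record@utr3[1L] + 1L
}

#' Write a TSV eligibility report
#'
#' One row per record: id, length, passed flag and comma-separated
#' failure codes.
#'
#' @param records list of [MRNARecord-class].
#' @param path output TSV path.
#' @param criteria a [filterCriteria()] list.
#' @return (invisibly) the report data.frame.
#' @export
writeFilterReport <- function(records, path, criteria = filterCriteria()) {
    rows <- lapply(records, function(r) {
        res <- checkEligibility(r, criteria)
        data.frame(id = r@id, length = nchar(r@sequence),
                   passed = res$passed,
                   failures = paste(res$failures, collapse = ","),
                   stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(df)
}
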