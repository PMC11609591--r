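#' Construct a SecondaryStructure
#'
#' @param sequence RNA string (DNA normalized).
#' @param pairs integer pairing table, \code{pairs[i]} = 1-based partner
#'   of position i or 0; must be an involution with no crossing pairs.
#' @param freeEnergy free energy in kcal/mol, \code{NA} when unknown.
#' @param engine provenance string.
#' @return a [SecondaryStructure-class].
#' @export
secondaryStructure <- function(sequence, pairs, freeEnergy = NA_real_,
                               engine = "unknown") {
    new("SecondaryStructure", sequence = normalizeRNA(sequence),
        pairs = as.integer(pairs), freeEnergy = as.numeric(freeEnergy),
        engine = engine)
}

#' @rdname accessors
setMethod("rnaSequence", "SecondaryStructure", function(x) x@sequence)
#' @rdname accessors
setMethod("pairTable", "SecondaryStructure", function(x) x@pairs)
#' @rdname accessors
setMethod("freeEnergy", "SecondaryStructure", function(x) x@freeEnergy)
#' @rdname accessors
setMethod("engineInfo", "SecondaryStructure", function(x) x@engine)

#' @describeIn accessors render the structure in dot-bracket notation.
setMethod("dotBracket", "SecondaryStructure", function(x) {
    p <- x@pairs
    out <- rep(".", length(p))
    out[p != 0 & p > seq_along(p)] <- "("
    out[p != 0 & p < seq_along(p)] <- ")"
    paste(out, collapse = "")
})

setMethod("show", "SecondaryStructure", function(object) {
    n <- nchar(object@sequence)
    cat(sprintf("SecondaryStructure: %d nt, %d base pairs, dG = %s kcal/mol\n",
                n, sum(object@pairs != 0) %/% 2,
                ifelse(is.na(object@freeEnergy), "NA",
                       sprintf("%.2f", object@freeEnergy))))
    cat("  engine:", object@engine, "\n")
    if (n <= 70) {
        cat(" ", object@sequence, "\n")
        cat(" ", dotBracket(object), "\n")
    }
})

## ---- engine --------------------------------------------------------------

#' ViennaRNA folding engine configuration
#'
#' The package delegates structure prediction to the ViennaRNA
#' command-line programs; this object pins which binaries and folding
#' temperature are used, and carries the detected version so that every
#' structure records its provenance.
#'
#' @param temperature folding temperature in Celsius (engine default 37).
#' @param rnafold,rnasubopt program names or paths.
#' @return a \code{FoldingEngine} list with the detected version.
#' @export
viennaEngine <- function(temperature = 37, rnafold = "RNAfold",
                         rnasubopt = "RNAsubopt") {
    structure(list(rnafold = rnafold, rnasubopt = rnasubopt,
                   temperature = temperature,
                   version = .engineVersion(rnafold)),
              class = "FoldingEngine")
}

.engineVersion <- function(rnafold) {
    if (Sys.which(rnafold) == "")
        return(NA_character_)
    out <- suppressWarnings(system2(rnafold, "--version", stdout = TRUE,
                                    stderr = FALSE))
    if (length(out)) sub("^RNAfold\\s+", "", out[1]) else NA_character_
}

.checkEngine <- function(engine) {
    stopifnot(inherits(engine, "FoldingEngine"))
    for (prog in c(engine$rnafold, engine$rnasubopt))
        if (Sys.which(prog) == "")
            stop("folding engine '", prog, "' not found on PATH; ",
                 "install the ViennaRNA package (https://www.tbi.univie.ac.at/RNA/)")
}

.engineProvenance <- function(engine, program) {
    sprintf("%s %s T=%gC", program, engine$version, engine$temperature)
}

.engineArgs <- function(engine) {
    if (engine$temperature != 37) c("-T", format(engine$temperature)) else character(0)
}

.runEngine <- function(prog, args, input) {
    errFile <- tempfile("engine-stderr-")
    on.exit(unlink(errFile))
    out <- suppressWarnings(system2(prog, args, input = input, stdout = TRUE,
                                    stderr = errFile))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
        diag <- tryCatch(readLines(errFile, warn = FALSE),
                         error = function(e) character(0))
        stop(prog, " failed (exit ", status, "): ",
             paste(utils::tail(diag, 5), collapse = "; "))
    }
    out
}

## trailing "( -12.30)" on a dot-bracket line
.splitEnergy <- function(line) {
    ## the energy group must contain a digit, so a trailing all-dot hairpin
    ## like "(....)" is never mistaken for an energy annotation
    m <- regmatches(line,
                    regexec("^([.()]+)\\s*\\(\\s*(-?[0-9]+(?:\\.[0-9]+)?)\\s*\\)\\s*$",
                            line))[[1]]
    if (length(m) == 3)
        list(db = m[2], energy = as.numeric(m[3]))
    else
        list(db = trimws(line), energy = NA_real_)
}

#' Predict the minimum free energy structure
#'
#' Runs RNAfold on one sequence and returns its single MFE structure at
#' the configured temperature (default 37 Celsius, the engine's
#' physiological default). Deterministic for a fixed engine version.
#'
#' @param sequence RNA string over {A,C,G,U} (DNA normalized).
#' @param engine a [viennaEngine()] configuration.
#' @return a [SecondaryStructure-class] with free energy and provenance.
#' @export
foldMFE <- function(sequence, engine = viennaEngine()) {
    .checkEngine(engine)
    sequence <- normalizeRNA(sequence)
    stopifnot(nchar(sequence) >= 1L)
    out <- .runEngine(engine$rnafold, c("--noPS", .engineArgs(engine)),
                      input = sequence)
    if (length(out) < 2)
        stop("unexpected RNAfold output: ", paste(out, collapse = " / "))
    se <- .splitEnergy(out[2])
    secondaryStructure(sequence, .dotBracketPairs(se$db), se$energy,
                       engine = .engineProvenance(engine, "RNAfold"))
}

#' Lowest free-energy suboptimal structures
#'
#' Returns the \code{k} lowest-energy structures of a sequence, sorted
#' by ascending free energy, with the MFE structure first. Structures
#' are enumerated with RNAsubopt inside an energy window above the MFE
#' that is doubled (from \code{window} kcal/mol) until at least
#' \code{k} structures exist.
#'
#' @param sequence RNA string.
#' @param k number of structures (>= 1).
#' @param engine a [viennaEngine()] configuration.
#' @param window starting energy window in kcal/mol.
#' @param maxWindow give up (error) once the window exceeds this.
#' @return list of \code{k} [SecondaryStructure-class], energies
#'   non-decreasing, first element the MFE structure.
#' @export
foldSuboptimal <- function(sequence, k = 5L, engine = viennaEngine(),
                           window = 0.1, maxWindow = 12.8) {
    .checkEngine(engine)
    k <- as.integer(k)
    stopifnot(k >= 1L)
    sequence <- normalizeRNA(sequence)
    mfe <- foldMFE(sequence, engine)
    if (k == 1L) return(list(mfe))

    prov <- .engineProvenance(engine, "RNAsubopt")
    repeat {
        out <- .runEngine(engine$rnasubopt,
                          c("-e", format(window), "-s", .engineArgs(engine)),
                          input = sequence)
        body <- grep("^[.()]+\\s+-?[0-9.]+\\s*$", out, value = TRUE)
        if (length(body) >= k || window >= maxWindow) break
        window <- window * 2
    }
    if (length(body) < k)
        stop("RNAsubopt found only ", length(body), " structures within ",
             window, " kcal/mol of the MFE; asked for ", k)
    fields <- strsplit(trimws(body), "\\s+")
    db <- vapply(fields, `[[`, character(1), 1L)
    en <- as.numeric(vapply(fields, `[[`, character(1), 2L))
    o <- order(en)
    db <- db[o]; en <- en[o]
    ## put the canonical MFE structure first among its energy ties
    i <- match(dotBracket(mfe), db)
    if (!is.na(i) && i > 1L) {
        db <- c(db[i], db[-i]); en <- c(en[i], en[-i])
    } else if (is.na(i)) {
        db <- c(dotBracket(mfe), db); en <- c(freeEnergy(mfe), en)
    }
    lapply(seq_len(k), function(j)
        secondaryStructure(sequence, .dotBracketPairs(db[j]), en[j],
                           engine = prov))
}

## ---- parsers -------------------------------------------------------------

.dotBracketPairs <- function(db) {
    chars <- strsplit(db, "")[[1]]
    bad <- which(!chars %in% c(".", "(", ")"))
    if (length(bad))
        stop("invalid dot-bracket character '", chars[bad[1]],
             "' at position ", bad[1])
    pairs <- integer(length(chars))
    stack <- integer(0)
    for (i in seq_along(chars)) {
        if (chars[i] == "(") {
            stack <- c(stack, i)
        } else if (chars[i] == ")") {
            if (length(stack) == 0L)
                stop("unbalanced ')' at position ", i)
            j <- stack[length(stack)]
            stack <- stack[-length(stack)]
            pairs[i] <- j; pairs[j] <- i
        }
    }
    if (length(stack))
        stop("unbalanced '(' at position ", stack[length(stack)])
    pairs
}

#' Parse Vienna-style dot-bracket text
#'
#' Accepts the two-line form (sequence line then structure line), an
#' optional leading \code{>id} header, and an optional trailing
#' \code{(-12.30)} free energy on the structure line.
#'
#' @param text character vector of lines, or one string with embedded
#'   newlines.
#' @return a [SecondaryStructure-class] (engine provenance
#'   \code{"dot-bracket input"}).
#' @examples
#' s <- parseDotBracket(c("GGGAAACCC", "(((...))) (-1.20)"))
#' pairTable(s)
#' @export
parseDotBracket <- function(text) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) && startsWith(lines[1], ">"))
        lines <- lines[-1]
    if (length(lines) < 2)
        stop("dot-bracket input needs a sequence line and a structure line")
    seq <- trimws(lines[1])
    se <- .splitEnergy(trimws(lines[2]))
    if (nchar(se$db) != nchar(seq))
        stop("sequence (", nchar(seq), " nt) and structure (", nchar(se$db),
             " positions) lengths differ")
    secondaryStructure(seq, .dotBracketPairs(se$db), se$energy,
                       engine = "dot-bracket input")
}

#' Parse an mfold CT (connectivity table) structure
#'
#' Standard 6-column CT body (index, base, previous, next, partner,
#' index) after a header line; partner column 0 means unpaired.
#' Inconsistent partner columns and crossing (pseudoknotted) pairs are
#' rejected.
#'
#' @param text character vector of CT lines (one structure).
#' @return a [SecondaryStructure-class] (engine provenance
#'   \code{"CT input"}).
#' @export
parseCT <- function(text) {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < 2)
        stop("CT input needs a header line and at least one body row")
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    n <- suppressWarnings(as.integer(header[1]))
    if (is.na(n) || n < 1)
        stop("CT header must start with the sequence length")
    energy <- NA_real_
    em <- regmatches(lines[1],
                     regexec("[dD]G\\s*=\\s*(-?[0-9.]+)", lines[1]))[[1]]
    if (length(em) == 2) energy <- as.numeric(em[2])
    body <- lines[-1]
    if (length(body) != n)
        stop("CT body has ", length(body), " rows but header declares ", n)
    fields <- strsplit(trimws(body), "\\s+")
    idx <- as.integer(vapply(fields, `[[`, character(1), 1L))
    base <- vapply(fields, `[[`, character(1), 2L)
    partner <- as.integer(vapply(fields, `[[`, character(1), 5L))
    if (!identical(idx, seq_len(n)))
        stop("CT rows are not numbered 1..n")
    for (i in seq_len(n)) {
        j <- partner[i]
        if (j != 0L && (j < 1L || j > n || partner[j] != i))
            stop("inconsistent CT partner columns: position ", i, " -> ", j,
                 " but ", j, " -> ", if (j >= 1 && j <= n) partner[j] else "?")
    }
    secondaryStructure(paste(base, collapse = ""), partner, energy,
                       engine = "CT input")
}

## ---- Vienna .fold file I/O ----------------------------------------------

#' Read a multi-record Vienna fold file
#'
#' Records of the form \code{>id} / sequence / dot-bracket (with
#' optional trailing energy); a bare two-line file is read as one
#' unnamed record.
#'
#' @param path input path.
#' @return named list of [SecondaryStructure-class].
#' @export
readFoldFile <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    heads <- grep("^>", lines)
    if (!length(heads)) {
        out <- list(parseDotBracket(lines))
        names(out) <- "structure1"
        return(out)
    }
    ends <- c(heads[-1] - 1L, length(lines))
    out <- mapply(function(s, e) parseDotBracket(lines[s:e]),
                  heads, ends, SIMPLIFY = FALSE)
    names(out) <- sub("^>\\s*", "", sub("\\s.*$", "", lines[heads]))
    out
}

#' Write structures to a Vienna fold file
#'
#' @param structures named list of [SecondaryStructure-class].
#' @param path output path.
#' @return (invisibly) the path.
#' @export
writeFoldFile <- function(structures, path) {
    nm <- names(structures)
    if (is.null(nm)) nm <- paste0("structure", seq_along(structures))
    txt <- vapply(seq_along(structures), function(i) {
        s <- structures[[i]]
        en <- if (is.na(freeEnergy(s))) ""
              else sprintf(" (%.2f)", freeEnergy(s))
        paste0(">", nm[i], "\n", rnaSequence(s), "\n", dotBracket(s), en)
    }, character(1))
    writeLines(txt, path)
    invisible(path)
}
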