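## run expr under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, expr) {
    if (is.null(seed))
        return(expr)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Generate uniform-composition random RNA sequences
#'
#' The random-sequence null model: i.i.d. draws over {A,C,G,U}. The
#' published control uses 50 sequences of 1600 nt with equal base
#' probabilities; those are therefore the defaults.
#'
#' @param count number of sequences (>= 0).
#' @param length sequence length in nt (>= 1).
#' @param baseProbs probabilities for A, C, G, U; must sum to 1.
#' @param seed integer seed for reproducibility; \code{NULL} uses the
#'   current RNG stream.
#' @return character vector of \code{count} RNA strings, named r1..rN.
#' @examples
#' s <- generateRandomSequences(3, 40, seed = 1)
#' nchar(s)
#' @export
generateRandomSequences <- function(count = 50L, length = 1600L,
                                    baseProbs = rep(0.25, 4), seed = NULL) {
    count <- as.integer(count); length <- as.integer(length)
    stopifnot(count >= 0L, length >= 1L)
    if (length(baseProbs) != 4L || any(baseProbs < 0) ||
        abs(sum(baseProbs) - 1) > 1e-9)
        stop("baseProbs must be 4 non-negative probabilities summing to 1")
    if (count == 0L) return(character(0))
    seqs <- .withSeed(seed, vapply(seq_len(count), function(i)
        paste(sample(RNA_ALPHABET, length, replace = TRUE, prob = baseProbs),
              collapse = ""),
        character(1)))
    names(seqs) <- paste0("r", seq_len(count))
    seqs
}

#' Generate a structure with known exterior-loop composition
#'
#' Builds a sequence/dot-bracket pair whose exterior loop contains
#' exactly \code{extUnpaired} unpaired nucleotides and
#' \code{topHelices} outermost helices, each a perfect stem of
#' \code{helixLen} Watson-Crick pairs closed by a \code{hairpinLen}-nt
#' terminal loop. Unpaired nucleotides are distributed as evenly as
#' possible over the \code{topHelices + 1} exterior gaps, 5' first.
#' The ground-truth link count \eqn{u + 2h - 1} is attached, which is
#' what makes these fixtures usable as an oracle for the exterior-loop
#' statistic.
#'
#' @param extUnpaired u, exterior unpaired nucleotide count (>= 0).
#' @param topHelices h, outermost helix count (>= 0); \code{u + h >= 1}.
#' @param helixLen base pairs per helix (>= 1).
#' @param hairpinLen nucleotides per terminal loop (>= 3, the sterically
#'   allowed minimum).
#' @param seed integer seed for the random base assignment.
#' @return list with elements \code{sequence}, \code{structure}
#'   (dot-bracket) and \code{linkCount} (the ground truth u + 2h - 1).
#' @examples
#' generateStructure(4, 1, helixLen = 2, hairpinLen = 3)$structure
#' # "..((...)).."
#' @export
generateStructure <- function(extUnpaired, topHelices, helixLen = 4L,
                              hairpinLen = 4L, seed = NULL) {
    u <- as.integer(extUnpaired); h <- as.integer(topHelices)
    stopifnot(u >= 0L, h >= 0L, helixLen >= 1L, hairpinLen >= 3L)
    if (u + h == 0L)
        stop("infeasible structure: extUnpaired + topHelices must be >= 1")
    gaps <- rep(u %/% (h + 1L), h + 1L)
    extra <- u %% (h + 1L)
    if (extra > 0L) gaps[seq_len(extra)] <- gaps[seq_len(extra)] + 1L
    helix <- paste0(strrep("(", helixLen), strrep(".", hairpinLen),
                    strrep(")", helixLen))
    parts <- character(2L * h + 1L)
    parts[seq(1L, 2L * h + 1L, by = 2L)] <- strrep(".", gaps)
    if (h > 0L) parts[seq(2L, 2L * h, by = 2L)] <- helix
    db <- paste(parts, collapse = "")

    wc <- list(A = "U", U = "A", G = "C", C = "G")
    chars <- strsplit(db, "")[[1]]
    seq <- .withSeed(seed, {
        out <- character(length(chars))
        stack <- integer(0)
        for (i in seq_along(chars)) {
            if (chars[i] == "(") stack <- c(stack, i)
            else if (chars[i] == ")") {
                j <- stack[length(stack)]; stack <- stack[-length(stack)]
                out[j] <- sample(RNA_ALPHABET, 1L)
                out[i] <- wc[[out[j]]]
            }
        }
        unp <- !nzchar(out)
        out[unp] <- sample(RNA_ALPHABET, sum(unp), replace = TRUE)
        paste(out, collapse = "")
    })
    list(sequence = seq, structure = db, linkCount = u + 2L * h - 1L)
}

#' Sample synthetic Gaussian contour-length values
#'
#' Draws from a normal distribution parameterized by the histogram-fit
#' convention used throughout the package: \code{center} is the mean
#' and \code{width} is the 1/e half-width w, so the standard deviation
#' is \eqn{w/\sqrt{2}}. Negative draws are rejected and redrawn since a
#' contour length is non-negative (negligible for the parameter regimes
#' of interest).
#'
#' @param n number of draws (>= 1).
#' @param center mean, nm.
#' @param width 1/e half-width w > 0, nm.
#' @param seed integer seed.
#' @return numeric vector of n non-negative contour lengths (nm).
#' @export
sampleGaussianCL <- function(n, center, width, seed = NULL) {
    n <- as.integer(n)
    stopifnot(n >= 1L)
    if (width <= 0) stop("width must be positive")
    .withSeed(seed, {
        out <- stats::rnorm(n, mean = center, sd = width / sqrt(2))
        while (any(neg <- out < 0))
            out[neg] <- stats::rnorm(sum(neg), mean = center,
                                     sd = width / sqrt(2))
        out
    })
}

#' Write sequences to a FASTA file
#'
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return (invisibly) the path.
#' @export
writeFasta <- function(sequences, path) {
    nm <- names(sequences)
    if (is.null(nm)) nm <- paste0("seq", seq_along(sequences))
    writeLines(paste0(">", nm, "\n", sequences), path)
    invisible(path)
}
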