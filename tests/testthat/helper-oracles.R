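# Independent brute-force oracle for the exterior-loop statistic: literally
# walk positions 1..n, collect exterior nodes (unpaired positions and the
# two closing nucleotides of each outermost helix, skipping everything a
# helix encloses); the link count is the number of connections traversed.
bruteExteriorLinks <- function(pairs) {
    n <- length(pairs)
    nodes <- integer(0)
    i <- 1L
    while (i <= n) {
        if (pairs[i] == 0L) {
            nodes <- c(nodes, i)
            i <- i + 1L
        } else {
            nodes <- c(nodes, i, pairs[i])
            i <- pairs[i] + 1L
        }
    }
    max(length(nodes) - 1L, 0L)
}

# dot-bracket -> pairs, written independently of the package parser
# (recursive matching rather than a stack scan)
brutePairs <- function(db) {
    chars <- strsplit(db, "")[[1]]
    pairs <- integer(length(chars))
    open <- integer(0)
    for (i in seq_along(chars)) {
        if (chars[i] == "(") open <- c(open, i)
        if (chars[i] == ")") {
            pairs[i] <- open[length(open)]
            pairs[open[length(open)]] <- i
            open <- open[-length(open)]
        }
    }
    pairs
}

# an eligible full-length synthetic mRNA record: 5'UTR / CDS / 3'UTR with a
# canonical PAS and a terminal poly-A run
randomEligibleRecord <- function(id, species = "XX", clade = "other",
                                 geneClass = "unknown", cdsLen = 150L) {
    rnd <- function(n) paste(sample(c("A", "C", "G", "U"), n, replace = TRUE),
                             collapse = "")
    utr5 <- rnd(50)
    cds <- rnd(cdsLen)
    utr3 <- paste0(rnd(40), "AAUAAA", rnd(12), strrep("A", 12))
    seq <- paste0(utr5, cds, utr3)
    n5 <- nchar(utr5); nc <- nchar(cds); n3 <- nchar(utr3)
    mrnaRecord(id, seq, speciesCode = species, clade = clade,
               geneClass = geneClass,
               utr5 = c(1L, n5), cds = c(n5 + 1L, n5 + nc),
               utr3 = c(n5 + nc + 1L, n5 + nc + n3), source = "synthetic")
}

extdata <- function(f) system.file("extdata", f, package = "endloop")
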