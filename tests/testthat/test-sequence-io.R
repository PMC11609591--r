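test_that("FASTA reading preserves entries and normalizes DNA to RNA", {
    recs <- readSequences(extdata("synthetic_mrna.fa"), "fasta")
    expect_length(recs, 2L)
    expect_equal(vapply(recs, seqId, character(1)), c("SYN001", "SYN002"))
    expect_false(any(grepl("T", vapply(recs, rnaSequence, character(1)))))

    tmp <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">x", "ACGT"), tmp)
    expect_equal(rnaSequence(readSequences(tmp, "fasta")[[1]]), "ACGU")
    expect_error(readSequences(tempfile(), "fasta"), "no such file")
})

test_that("GenBank feature spans are extracted and ordered", {
    recs <- readSequences(extdata("synthetic_mrna.gb"), "genbank")
    expect_length(recs, 2L)
    r <- recs[[1]]
    expect_equal(utr5Span(r), c(1L, 60L))
    expect_equal(cdsSpan(r), c(61L, 300L))
    expect_equal(utr3Span(r), c(301L, 391L))
    expect_equal(nchar(rnaSequence(r)), 391L)
    expect_true(grepl("synthetic construct", r@source))
    # second record carries no UTR features
    expect_length(utr5Span(recs[[2]]), 0L)

    tmp <- withr::local_tempfile(fileext = ".gb")
    writeLines(c("LOCUS  BAD  10 bp", "ORIGIN", "//"), tmp)
    expect_error(readSequences(tmp, "genbank"), "BAD")
    writeLines("not a genbank file", tmp)
    expect_error(readSequences(tmp, "genbank"), "LOCUS")
})

test_that("eligibility accumulates every failure and accepts full-length mRNAs", {
    set.seed(1)
    ok <- randomEligibleRecord("hamp_like")  # UTR5 + CDS + PAS-bearing UTR3
    expect_equal(nchar(rnaSequence(ok)), 50L + 150L + 70L)
    res <- checkEligibility(ok)
    expect_true(res$passed)
    expect_length(res$failures, 0L)

    short <- mrnaRecord("s", strrep("ACGU", 37), source = "synthetic") # 148 nt
    rs <- checkEligibility(short)
    expect_false(rs$passed)
    expect_true(all(c("TOO_SHORT", "NO_UTR5", "NO_UTR3") %in% rs$failures))

    long <- mrnaRecord("l", paste0(strrep("ACGU", 1875), "AAUAAA",
                                   strrep("A", 10)))  # 7516 nt
    expect_true("TOO_LONG" %in% checkEligibility(long)$failures)

    # PAS searched inside the annotated 3'UTR only
    n <- nchar(rnaSequence(ok))
    noPas <- mrnaRecord("p", gsub("AAUAAA", "CCCCCC", rnaSequence(ok)),
                        utr5 = utr5Span(ok), cds = cdsSpan(ok),
                        utr3 = utr3Span(ok))
    expect_true("NO_PAS" %in% checkEligibility(noPas)$failures)

    # poly-A start: >= 8 consecutive A at the 3' terminus
    noTail <- mrnaRecord("t", paste0(substr(rnaSequence(ok), 1, n - 12), "GCGCGCGCGCGC"),
                         utr5 = utr5Span(ok), cds = cdsSpan(ok),
                         utr3 = utr3Span(ok))
    expect_true("NO_POLYA_START" %in% checkEligibility(noTail)$failures)
})

test_that("records passing strict criteria pass any strictly looser criteria", {
    set.seed(7)
    strict <- filterCriteria()
    loose <- filterCriteria(minLen = 100, maxLen = 10000, requireUTRs = FALSE,
                            checkPAS = FALSE, checkPolyA = FALSE)
    for (i in 1:20) {
        rec <- randomEligibleRecord(paste0("r", i),
                                    cdsLen = sample(100:2000, 1))
        if (checkEligibility(rec, strict)$passed)
            expect_true(checkEligibility(rec, loose)$passed)
    }
})

test_that("gcContent matches direct counting and complements AT content", {
    expect_equal(gcContent("GCGC"), 100)
    expect_equal(gcContent("AUAU"), 0)
    expect_equal(gcContent("GCAU"), 50)
    expect_error(gcContent(""), "empty")
    set.seed(3)
    for (i in 1:25) {
        s <- paste(sample(c("A", "C", "G", "U"), sample(1:500, 1),
                          replace = TRUE), collapse = "")
        counts <- table(factor(strsplit(s, "")[[1]],
                               levels = c("A", "C", "G", "U")))
        gc <- 100 * (counts[["G"]] + counts[["C"]]) / nchar(s)
        at <- 100 * (counts[["A"]] + counts[["U"]]) / nchar(s)
        expect_equal(gcContent(s), gc)
        expect_equal(gcContent(s) + at, 100)
        expect_gte(gcContent(s), 0)
        expect_lte(gcContent(s), 100)
    }
})

test_that("utr3Length is the closed-interval width, NA when unannotated", {
    r <- mrnaRecord("x", strrep("A", 400), utr5 = c(1, 50), cds = c(51, 300),
                    utr3 = c(301, 391))
    expect_equal(utr3Length(r), 91L)
    r1 <- mrnaRecord("y", strrep("A", 120), utr3 = c(100, 100))
    expect_equal(utr3Length(r1), 1L)
    expect_true(is.na(utr3Length(mrnaRecord("z", "ACGU"))))
})

test_that("poly-A trimming removes only a terminal run of >= minRun A", {
    expect_equal(trimPolyATail(paste0("GCGC", strrep("A", 20))), "GCGC")
    s <- paste0("GCGC", strrep("A", 5))
    expect_equal(trimPolyATail(s), s)   # run too short, kept
    expect_equal(trimPolyATail("GCAAAAAAAAGC"), "GCAAAAAAAAGC") # internal run kept
})

test_that("invalid records are rejected at construction", {
    expect_error(mrnaRecord("b", "ACGX"), "non-ACGT/U")
    expect_error(mrnaRecord("b", "ACGUACGU", utr5 = c(5, 8), cds = c(1, 2),
                            utr3 = c(3, 4)), "ordered")
    expect_error(mrnaRecord("b", "ACGU", utr3 = c(2, 10)), "beyond")
})

test_that("the filter report lists every record with its reason codes", {
    recs <- readSequences(extdata("synthetic_mrna.gb"), "genbank")
    tmp <- withr::local_tempfile(fileext = ".tsv")
    df <- writeFilterReport(recs, tmp)
    back <- read.delim(tmp)
    expect_equal(nrow(back), 2L)
    expect_true(back$passed[back$id == "SYN001"])
    expect_match(back$failures[back$id == "SYN002"], "TOO_SHORT")
})
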