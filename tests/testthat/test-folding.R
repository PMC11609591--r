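# Golden values below are keyed to the pinned engine version: a changed
# engine must fail these tests loudly rather than silently shift C_L values.
PINNED_ENGINE_VERSION <- "2.7.2"

test_that("the folding engine is present and at the pinned version", {
    eng <- viennaEngine()
    expect_false(is.na(eng$version))
    expect_identical(eng$version, PINNED_ENGINE_VERSION)
})

test_that("MFE folding matches engine golden values", {
    # homopolymer A has no Watson-Crick partner: all unpaired
    s <- foldMFE("AAAAAAAAAA")
    expect_equal(pairTable(s), rep(0L, 10))
    expect_match(engineInfo(s), "RNAfold 2\\.7\\.2")

    # toy hairpin golden file
    hp <- foldMFE("GGGGAAAACCCC")
    expect_equal(dotBracket(hp), "((((....))))")
    expect_equal(freeEnergy(hp), -5.40)

    # DNA input accepted and normalized before folding
    expect_equal(dotBracket(foldMFE("GGGGAAAACCCC")),
                 dotBracket(foldMFE("ggggaaaacccc")))
})

test_that("a 1600-nt random sequence folds with negative free energy", {
    s <- generateRandomSequences(1, 1600, seed = 11)
    mfe <- foldMFE(s[[1]])
    expect_lt(freeEnergy(mfe), 0)
    expect_gt(sum(pairTable(mfe) != 0), 0)
})

test_that("suboptimal structures are sorted with the MFE structure first", {
    sub1 <- foldSuboptimal("GGGGAAAACCCC", k = 1)
    expect_length(sub1, 1L)
    expect_equal(dotBracket(sub1[[1]]), dotBracket(foldMFE("GGGGAAAACCCC")))

    sub5 <- foldSuboptimal("GGGGAAAACCCC", k = 5)
    expect_length(sub5, 5L)
    en <- vapply(sub5, freeEnergy, numeric(1))
    expect_true(all(diff(en) >= 0))
    expect_equal(dotBracket(sub5[[1]]), "((((....))))")
    # golden file for the pinned engine
    expect_equal(vapply(sub5, dotBracket, character(1)),
                 c("((((....))))", "(((.....))).", ".(((....))).",
                   "(((......)))", ".(((.....)))"))
    expect_equal(en, c(-5.4, -4.2, -3.1, -2.7, -2.4))

    # a 200-nt sequence: sort contract only
    s <- generateRandomSequences(1, 200, seed = 3)
    sub <- foldSuboptimal(s[[1]], k = 5)
    expect_length(sub, 5L)
    expect_true(all(diff(vapply(sub, freeEnergy, numeric(1))) >= 0))
    expect_equal(dotBracket(sub[[1]]), dotBracket(foldMFE(s[[1]])))
})

test_that("dot-bracket parsing builds the pairing table and captures energy", {
    s <- parseDotBracket(c("GGGAAACCC", "(((...)))"))
    expect_equal(pairTable(s), c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 1L))
    expect_true(is.na(freeEnergy(s)))

    s2 <- parseDotBracket(c(">id desc", "GGGAAACCC", "(((...))) (-1.20)"))
    expect_equal(freeEnergy(s2), -1.2)
    expect_equal(pairTable(s2), pairTable(s))

    expect_equal(pairTable(parseDotBracket(c("AAA", "..."))), rep(0L, 3))
    expect_error(parseDotBracket(c("AAA", "((.")), "unbalanced '\\(' at position")
    expect_error(parseDotBracket(c("AAA", ".))")), "unbalanced '\\)' at position 2")
    expect_error(parseDotBracket(c("AAAA", "...")), "lengths differ")
    expect_error(parseDotBracket(c("AAA", ".x.")), "invalid dot-bracket")
})

test_that("CT parsing agrees with dot-bracket on the same structure", {
    ct <- parseCT(readLines(extdata("example.ct")))
    db <- parseDotBracket(c("GGGAAACCC", "(((...)))"))
    expect_equal(pairTable(ct), pairTable(db))
    expect_equal(rnaSequence(ct), "GGGAAACCC")
    expect_equal(freeEnergy(ct), -1.2)

    allZero <- c("4 synthetic", paste(1:4, c("A", "C", "G", "U"), 0:3,
                                      c(2:4, 0), 0, 1:4))
    expect_equal(pairTable(parseCT(allZero)), rep(0L, 4))

    # i -> j with j -> k != i
    bad <- c("4 x", "1 A 0 2 3 1", "2 C 1 3 0 2", "3 G 2 4 2 3",
             "4 U 3 0 0 4")
    expect_error(parseCT(bad), "inconsistent")

    # crossing pairs (1,5) and (3,8): a pseudoknot must be rejected
    partner <- c(5L, 0L, 8L, 0L, 1L, 0L, 0L, 3L)
    pk <- c("8 x", paste(1:8, "G", 0:7, c(2:8, 0), partner, 1:8))
    expect_error(parseCT(pk), "pseudoknot|crossing")
})

test_that("rendering and parsing round-trip every generated structure", {
    set.seed(4)
    for (i in 1:25) {
        g <- generateStructure(sample(0:20, 1), sample(1:5, 1),
                               helixLen = sample(1:6, 1),
                               hairpinLen = sample(3:6, 1),
                               seed = sample.int(1e6, 1))
        s <- parseDotBracket(c(g$sequence, g$structure))
        expect_identical(dotBracket(s), g$structure)
        expect_identical(pairTable(s), brutePairs(g$structure))
        rt <- parseDotBracket(c(rnaSequence(s), dotBracket(s)))
        expect_identical(pairTable(rt), pairTable(s))
    }
})

test_that("fold files round-trip through write and read", {
    structs <- readFoldFile(extdata("example.fold"))
    expect_named(structs, c("hairpin", "openchain", "twohelix"))
    tmp <- withr::local_tempfile(fileext = ".fold")
    writeFoldFile(structs, tmp)
    back <- readFoldFile(tmp)
    expect_equal(lapply(back, pairTable), lapply(structs, pairTable))
    expect_equal(vapply(back, freeEnergy, numeric(1)),
                 vapply(structs, freeEnergy, numeric(1)))
})

test_that("structure validity rejects broken pairing tables", {
    expect_error(secondaryStructure("ACGU", c(3, 0, 0, 0)), "involution")
    expect_s4_class(secondaryStructure("AU", c(2, 1)), "SecondaryStructure")
    expect_error(secondaryStructure("ACGU", c(1, 0, 0, 0)), "itself")
    expect_error(secondaryStructure("ACGUACGU",
                                    c(5L, 0L, 8L, 0L, 1L, 0L, 0L, 3L)),
                 "pseudoknot")
})
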