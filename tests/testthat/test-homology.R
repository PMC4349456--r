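data(BLOSUM62, package = "Biostrings", envir = environment())

test_that("self-alignment spans the sequence at 100% identity", {
    s <- "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ"
    aln <- smithWaterman(s, s)
    expect_equal(aln@pctIdentity, 100)
    expect_identical(aln@alignedA, s)
    expect_identical(c(aln@startA, aln@endA), c(1L, nchar(s)))
})

test_that("score and reported alignment agree with the exhaustive DP oracle", {
    # DNA-letter pair under a +3/-3 match matrix, all letters valid residues
    letters4 <- c("A", "C", "G", "T")
    mat <- matrix(-3, 4, 4, dimnames = list(letters4, letters4))
    diag(mat) <- 3
    sc <- alignmentScoring(mat, gapOpen = 2, gapExtend = 2, swFloor = 0)
    aln <- smithWaterman("TGTTACGG", "GGTTGACTA", sc)
    oracle <- swOracleScore("TGTTACGG", "GGTTGACTA", mat, 2, 2)
    expect_equal(aln@score, oracle)
    # the reported traceback must rescore to the reported score
    expect_equal(scoreAlignedStrings(aln@alignedA, aln@alignedB, mat, 2, 2),
                 aln@score)
})

test_that("random short pairs match the DP oracle and are symmetric", {
    set.seed(11)
    sc <- alignmentScoring(swFloor = 0)
    for (i in 1:50) {
        a <- randomProteinStr(sample(3:12, 1))
        b <- randomProteinStr(sample(3:12, 1))
        ab <- smithWaterman(a, b, sc)
        expect_equal(ab@score, swOracleScore(a, b, BLOSUM62, 11, 1),
                     info = paste(a, b))
        expect_equal(ab@score, smithWaterman(b, a, sc)@score)
        expect_equal(scoreAlignedStrings(ab@alignedA, ab@alignedB,
                                         BLOSUM62, 11, 1),
                     ab@score, info = paste(a, b))
    }
})

test_that("unknown residues score through the X column; empty input errors", {
    ref <- smithWaterman("MKTXYIAK", "MKTXYIAK")
    odd <- smithWaterman("MKT8YIAK", "MKTJYIAK")  # neither in BLOSUM62
    expect_equal(odd@score, ref@score)
    expect_error(smithWaterman("", "MKT"), "empty")
})

test_that("NCBI-format matrix files load and score identically", {
    path <- tempfile(fileext = ".txt")
    letters4 <- rownames(BLOSUM62)[1:20]
    writeLines(c(
        "# reduced BLOSUM62",
        paste(" ", paste(letters4, collapse = " ")),
        vapply(letters4, function(r)
            paste(r, paste(BLOSUM62[r, letters4], collapse = " ")),
            character(1))), path)
    mat <- readSubstitutionMatrix(path)
    expect_equal(mat, BLOSUM62[letters4, letters4] * 1.0)
})

test_that("best-best flags require mutual best hits", {
    # one identical protein in each genome -> a single best_best pair
    p <- randomProteinStr(60)
    co <- coordSeq(1)
    gA <- toyGenome(cbind(data.frame(locus = "a1"), co), org = "aaa",
                    seqs = c(a1 = p))
    gB <- toyGenome(cbind(data.frame(locus = "b1"), co), org = "bbb",
                    seqs = c(b1 = p))
    rec <- bestBestHits(list(gA, gB))
    expect_identical(nrow(rec), 1L)
    expect_true(rec$best_best)
    expect_equal(rec$pct_identity, 100)

    # a's best in B is b, but b's best in A is a2 -> (a,b) not best_best
    set.seed(3)
    base <- randomProteinStr(80)
    a1 <- funcdisc:::.mutateProtein(base, 0.25)
    co2 <- coordSeq(2)
    gA2 <- toyGenome(cbind(data.frame(locus = c("a1", "a2")), co2),
                     org = "aaa", seqs = c(a1 = a1, a2 = base))
    gB2 <- toyGenome(cbind(data.frame(locus = "b1"), coordSeq(1)),
                     org = "bbb", seqs = c(b1 = base))
    rec2 <- bestBestHits(list(gA2, gB2))
    flag <- stats::setNames(rec2$best_best, rec2$gene_a)
    expect_true(flag[["aaa:a2"]])
    expect_false(flag[["aaa:a1"]])
})

test_that("empty proteomes contribute nothing, with a warning", {
    p <- randomProteinStr(60)
    g1 <- toyGenome(cbind(data.frame(locus = "a1"), coordSeq(1)),
                    org = "aaa", seqs = c(a1 = p))
    g2 <- toyGenome(cbind(data.frame(locus = "b1"), coordSeq(1)),
                    org = "bbb", seqs = c(b1 = p))
    g3 <- suppressWarnings(
        toyGenome(cbind(data.frame(locus = "c1"), coordSeq(1)),
                  org = "ccc", seqs = c(zz = p)))
    expect_warning(rec <- bestBestHits(list(g1, g2, g3)), "empty proteome")
    expect_identical(nrow(rec), 1L)
})

test_that("selectHomologs applies cutoff, ranking, ties and truncation", {
    rec <- data.frame(
        gene_a = "qqq:q1",
        gene_b = c("aaa:x", "bbb:x", "ccc:x", "ddd:x", "eee:x"),
        sw_score = c(500L, 400L, 400L, 300L, 900L),
        pct_identity = c(80, 55, 55, 41, 35),
        best_best = c(TRUE, TRUE, TRUE, TRUE, TRUE),
        stringsAsFactors = FALSE)
    rec$best_best[4] <- TRUE
    q <- homologQuery("qqq:q1", nHomologs = 100, aaIdc = 40)
    # eee fails the identity cutoff even with the top score
    expect_identical(selectHomologs(q, rec),
                     c("qqq:q1", "aaa:x", "bbb:x", "ccc:x", "ddd:x"))
    # equal scores resolve lexicographically (bbb before ccc)
    expect_identical(selectHomologs(homologQuery("qqq:q1", nHomologs = 2),
                                    rec),
                     c("qqq:q1", "aaa:x", "bbb:x"))
    # a 100% cutoff with no identical partner returns only the query
    expect_identical(selectHomologs(homologQuery("qqq:q1", aaIdc = 100),
                                    rec),
                     "qqq:q1")
    # non-best-best records never qualify
    rec$best_best <- FALSE
    expect_identical(selectHomologs(q, rec), "qqq:q1")
})

test_that("homolog sets shrink with aaIdc and grow with nHomologs", {
    pg <- generatePangenome(fixtureConfig(nGenomes = 8,
                                          genesPerGenome = 20, seed = 21))
    sizes <- vapply(c(20, 40, 60, 90, 99.9), function(idc)
        length(selectHomologs(homologQuery(pg$queryGeneId, aaIdc = idc),
                              pg$similarity)), integer(1))
    expect_true(all(diff(sizes) <= 0))
    byN <- vapply(c(1, 3, 5, 100), function(nh)
        length(selectHomologs(homologQuery(pg$queryGeneId, nHomologs = nh),
                              pg$similarity)), integer(1))
    expect_true(all(diff(byN) >= 0))
})
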