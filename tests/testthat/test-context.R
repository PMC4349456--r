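# a 10-gene genome used across window tests; ECs on alternating genes
windowGenome <- function(n = 10, topology = "linear") {
    tab <- cbind(data.frame(locus = sprintf("g%d", 0:(n - 1))), coordSeq(n))
    tab$topology <- topology
    tab$ec <- ifelse(0:(n - 1) %% 2 == 0, sprintf("1.1.1.%d", 0:(n - 1)), "")
    toyGenome(tab)
}

test_that("windows truncate on linear replicons and wrap on circular ones", {
    lin <- windowGenome(8, "linear")
    nb0 <- extractNeighborhood(lin, "tst:g5", 0)
    expect_identical(genes(nb0)$gene_id, "tst:g5")

    nbAll <- extractNeighborhood(lin, "tst:g5", 10)
    expect_identical(genes(nbAll)$index, 0:7)

    circ <- windowGenome(10, "circular")
    nb <- extractNeighborhood(circ, "tst:g0", 3)
    expect_identical(genes(nb)$index, c(7L, 8L, 9L, 0L, 1L, 2L, 3L))

    # window larger than the replicon: every gene exactly once
    nbBig <- extractNeighborhood(circ, "tst:g0", 30)
    expect_identical(sort(genes(nbBig)$index), 0:9)

    expect_error(extractNeighborhood(lin, "tst:nope", 2), "not found")
})

test_that("enzyme frequency is per-neighborhood presence, duplicates ignored", {
    tab <- cbind(data.frame(locus = sprintf("g%d", 1:9)), coordSeq(9))
    # anchors g2, g5, g8 with windows of 1: EC 1.1.1.103 flanks g2 twice
    # and g5 once; nothing around g8
    tab$ec <- c("1.1.1.103", "", "1.1.1.103", "1.1.1.103", "", "", "", "", "")
    g <- toyGenome(tab)
    nbs <- toyNeighborhoods(g, c("tst:g2", "tst:g5", "tst:g8"), 1)
    enz <- summarizeEnzymes(nbs)
    expect_identical(enz$ec, "1.1.1.103")
    expect_identical(enz$frequency, 2L)
    expect_identical(enz$support, "tst:g2,tst:g5")
})

test_that("a neighborhood set without any EC yields empty tables that still render", {
    tab <- cbind(data.frame(locus = sprintf("g%d", 1:4)), coordSeq(4))
    g <- toyGenome(tab)
    nbs <- toyNeighborhoods(g, "tst:g2", 2)
    enz <- summarizeEnzymes(nbs)
    expect_identical(nrow(enz), 0L)
    ref <- toyReference("1.1.1.1", "PX")
    met <- summarizeMetabolites(enz, nbs, ref)
    pat <- summarizePathways(enz, met, ref)
    expect_identical(nrow(met), 0L)
    expect_identical(nrow(pat), 0L)
    res <- new("NeighborhoodAnalysis", query = homologQuery("tst:g2"),
               homologs = "tst:g2", neighborhoods = nbs,
               enzymeSummary = enz, metaboliteSummary = met,
               pathwaySummary = pat, scoreMode = "weighted")
    out <- tempfile(fileext = ".html")
    renderHtml(res, out)
    expect_true(file.size(out) > 0)
})

test_that("a planted EC present in most neighborhoods outranks sparse decoys", {
    n <- 10
    tab <- cbind(data.frame(locus = sprintf("g%d", seq_len(n))),
                 coordSeq(n))
    # planted EC next to 8 of 10 anchors' windows; decoy next to 2
    tab$ec <- c(rep("9.9.9.1", 8), "8.8.8.1", "8.8.8.1")
    g <- toyGenome(tab)
    nbs <- toyNeighborhoods(g, sprintf("tst:g%d", seq_len(n)), 0)
    enz <- summarizeEnzymes(nbs)
    expect_identical(enz$ec[1], "9.9.9.1")
    expect_identical(enz$frequency, c(8L, 2L))
})

test_that("metabolite frequencies count neighborhoods, not enzyme copies", {
    # one EC with reaction A + B -> C, present around all 4 anchors
    tab <- cbind(data.frame(locus = sprintf("g%d", 1:4)), coordSeq(4))
    tab$ec <- rep("1.1.1.1", 4)
    g <- toyGenome(tab)
    nbs <- toyNeighborhoods(g, sprintf("tst:g%d", 1:4), 0)
    ref <- metabolicReference(
        ecToReactions = list("1.1.1.1" = "R1"),
        reactions = list(R1 = list(substrates = c("A", "B"),
                                   products = "C")))
    enz <- summarizeEnzymes(nbs)
    met <- summarizeMetabolites(enz, nbs, ref)
    expect_setequal(met$compound, c("A", "B", "C"))
    expect_identical(met$frequency, c(4L, 4L, 4L))

    # exclusion list removes currency metabolites
    met2 <- summarizeMetabolites(enz, nbs, ref, exclude = "A")
    expect_false("A" %in% met2$compound)
})

test_that("two enzymes sharing a compound count each neighborhood once", {
    # five anchors; EC1 near three of them, EC2 near three, overlapping at g3
    tab <- cbind(data.frame(locus = sprintf("g%d", 1:5)), coordSeq(5))
    tab$ec <- c("1.1.1.1", "1.1.1.1", "1.1.1.1;2.2.2.2", "2.2.2.2",
                "2.2.2.2")
    g <- toyGenome(tab)
    nbs <- toyNeighborhoods(g, sprintf("tst:g%d", 1:5), 0)
    ref <- metabolicReference(
        ecToReactions = list("1.1.1.1" = "R1", "2.2.2.2" = "R2"),
        reactions = list(R1 = list(substrates = "S1", products = "SHARED"),
                         R2 = list(substrates = "S2", products = "SHARED")))
    enz <- summarizeEnzymes(nbs)
    met <- summarizeMetabolites(enz, nbs, ref)
    got <- stats::setNames(met$frequency, met$compound)
    expect_identical(got[["SHARED"]], 5L)  # union, not 3 + 3
    expect_identical(got[["S1"]], 3L)
    expect_identical(got[["S2"]], 3L)
    oracle <- recountMetabolites(nbs, ref)
    expectSummaryEqual(met, oracle, "compound", "frequency")
})

test_that("pathway hits sum mapped enzyme and metabolite frequencies", {
    enz <- data.frame(ec = "1.1.1.1", frequency = 3L, name = "",
                      support = "x", stringsAsFactors = FALSE)
    met <- data.frame(compound = c("C1", "C2"), frequency = c(3L, 3L),
                      name = "", support = "x", stringsAsFactors = FALSE)
    ref <- metabolicReference(
        ecToReactions = list("1.1.1.1" = "R1"),
        reactions = list(R1 = list(substrates = "C1", products = "C2")),
        ecToPathways = list("1.1.1.1" = "P1"),
        compoundToPathways = list(C1 = "P1", C2 = "P1"))
    pat <- summarizePathways(enz, met, ref)
    expect_identical(pat$pathway, "P1")
    expect_identical(pat$hits, 9L)  # 3 + 3 + 3
    patD <- summarizePathways(enz, met, ref, scoreMode = "distinct")
    expect_identical(patD$hits, 3L)  # EC, C1, C2

    # enzymes with no pathway mapping leave the table empty
    refNone <- metabolicReference(
        ecToReactions = list("1.1.1.1" = "R1"),
        reactions = list(R1 = list(substrates = "C1", products = "C2")))
    patE <- summarizePathways(enz, met, refNone)
    expect_identical(nrow(patE), 0L)
})

test_that("runAnalysis is deterministic and window-monotone", {
    pg <- generatePangenome(fixtureConfig(nGenomes = 10,
                                          genesPerGenome = 30, seed = 33))
    q5 <- homologQuery(pg$queryGeneId, nNeighbors = 5)
    q20 <- homologQuery(pg$queryGeneId, nNeighbors = 20)
    r5 <- runAnalysis(q5, pg)
    r20 <- runAnalysis(q20, pg)
    f5 <- stats::setNames(enzymeSummary(r5)$frequency,
                          enzymeSummary(r5)$ec)
    f20 <- stats::setNames(enzymeSummary(r20)$frequency,
                           enzymeSummary(r20)$ec)
    expect_true(all(names(f5) %in% names(f20)))
    expect_true(all(f20[names(f5)] >= f5))

    again <- runAnalysis(q5, pg)
    expect_identical(enzymeSummary(again), enzymeSummary(r5))
    expect_identical(metaboliteSummary(again), metaboliteSummary(r5))
    expect_identical(pathwaySummary(again), pathwaySummary(r5))

    # every frequency is bounded by the number of neighborhoods
    expect_true(all(enzymeSummary(r20)$frequency <=
                    length(neighborhoods(r20))))
    expect_true(all(metaboliteSummary(r20)$frequency <=
                    length(neighborhoods(r20))))
})

test_that("a single-genome datastore analyzes only the query's own window", {
    pg <- generatePangenome(fixtureConfig(nGenomes = 1,
                                          genesPerGenome = 20, seed = 2,
                                          conservationProb = 1))
    res <- runAnalysis(homologQuery(pg$queryGeneId), pg)
    expect_identical(homologs(res), pg$queryGeneId)
    expect_length(neighborhoods(res), 1L)
    expect_error(runAnalysis(homologQuery("sp01:absent"), pg), "not found")
})

test_that("summary tables equal a brute-force recount on a full pangenome", {
    pg <- generatePangenome(fixtureConfig(nGenomes = 12,
                                          genesPerGenome = 40, seed = 44))
    res <- runAnalysis(homologQuery(pg$queryGeneId), pg)
    nbs <- neighborhoods(res)
    ecO <- recountEnzymes(nbs)
    cpO <- recountMetabolites(nbs, pg$reference)
    paO <- recountPathways(ecO, cpO, pg$reference)
    expectSummaryEqual(enzymeSummary(res), ecO, "ec", "frequency")
    expectSummaryEqual(metaboliteSummary(res), cpO, "compound", "frequency")
    expectSummaryEqual(pathwaySummary(res), paO, "pathway", "hits")
})
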