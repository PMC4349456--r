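gffLine <- function(seqid, start, end, attrs, type = "CDS", strand = "+") {
    paste(seqid, "test", type, start, end, ".", strand, "0", attrs,
          sep = "\t")
}

test_that("GFF3 genes are indexed by start coordinate, not file order", {
    gff <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        gffLine("chr1", 100, 300, "ID=a;locus_tag=a;product=p1"),
        gffLine("chr1", 900, 1100, "ID=b;locus_tag=b;product=p2"),
        gffLine("chr1", 400, 600, "ID=c;locus_tag=c;product=p3")), gff)
    g <- loadGenome(gff, orgCode = "tst")
    gr <- genes(g)
    expect_identical(gr$index[match(c("tst:a", "tst:b", "tst:c"),
                                    gr$gene_id)],
                     c(0L, 2L, 1L))
    expect_identical(replicons(g)$topology, "linear")
})

test_that("eC_number attributes become validated EC sets", {
    gff <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        gffLine("chr1", 10, 50,
                "ID=a;locus_tag=tdh;eC_number=1.1.1.103;product=L-threonine 3-dehydrogenase"),
        gffLine("chr1", 100, 150,
                "ID=b;locus_tag=two;eC_number=2.3.1.29,2.7.1.39;product=x"),
        gffLine("chr1", 200, 250,
                "ID=c;locus_tag=bad;eC_number=not-an-ec;product=y")), gff)
    expect_warning(g <- loadGenome(gff, orgCode = "tst"), "malformed EC")
    gr <- genes(g)
    expect_identical(unlist(gr$ec_numbers[gr$gene_id == "tst:tdh"]),
                     "1.1.1.103")
    expect_setequal(unlist(gr$ec_numbers[gr$gene_id == "tst:two"]),
                    c("2.3.1.29", "2.7.1.39"))
    expect_length(unlist(gr$ec_numbers[gr$gene_id == "tst:bad"]), 0L)
})

test_that("empty annotation yields an empty genome; duplicates are fatal", {
    gff <- tempfile(fileext = ".gff3")
    writeLines("##gff-version 3", gff)
    g <- loadGenome(gff, orgCode = "tst")
    expect_length(genes(g), 0L)
    expect_identical(nrow(replicons(g)), 0L)

    dup <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        gffLine("chr1", 10, 50, "ID=a;locus_tag=same"),
        gffLine("chr1", 100, 150, "ID=b;locus_tag=same")), dup)
    expect_error(loadGenome(dup, orgCode = "tst"), "duplicate locus_tag")
})

test_that("circularity is read from Is_circular region features", {
    gff <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        gffLine("chr1", 1, 5000, "ID=chr1;Is_circular=true",
                type = "region"),
        gffLine("chr1", 10, 50, "ID=a;locus_tag=a")), gff)
    g <- loadGenome(gff, orgCode = "tst")
    expect_identical(replicons(g)$topology, "circular")
})

test_that("genome write/load round-trips and ignores input row order", {
    set.seed(42)
    for (rep in 1:3) {
        n <- sample(4:9, 1)
        co <- coordSeq(n)
        tab <- data.frame(
            locus = sprintf("g%02d", seq_len(n)),
            start = co$start, end = co$end,
            product = sprintf("prod%d", seq_len(n)),
            ec = ifelse(seq_len(n) %% 2 == 0,
                        sprintf("1.2.3.%d", seq_len(n)), ""),
            stringsAsFactors = FALSE)
        seqs <- stats::setNames(
            vapply(seq_len(n), function(i) randomProteinStr(30),
                   character(1)),
            tab$locus)
        shuffled <- tab[sample(n), ]
        g1 <- toyGenome(tab, seqs = seqs)
        g2 <- toyGenome(shuffled, seqs = seqs)
        expect_identical(genes(g1), genes(g2))

        out <- tempfile(fileext = ".tsv")
        faa <- tempfile(fileext = ".faa")
        writeGenome(g1, out, faa)
        g3 <- loadGenome(out, faa, orgCode = "tst")
        expect_identical(genes(g1), genes(g3))
        expect_identical(as.character(proteome(g1)),
                         as.character(proteome(g3)))
        expect_identical(replicons(g1), replicons(g3))
    }
})

test_that("genes without a protein sequence are kept with a warning", {
    tab <- cbind(data.frame(locus = c("a", "b")), coordSeq(2))
    expect_warning(
        g <- toyGenome(tab, seqs = c(a = "MKTAYIAK")),
        "no protein sequence")
    expect_identical(Biostrings::width(proteome(g))[
        names(proteome(g)) == "tst:b"], 0L)
    expect_length(genes(g), 2L)
})

test_that("reference loads ECs absent from the pathway map (transporter case)", {
    ref <- metabolicReference(
        ecToReactions = list("3.6.3.29" = "R001"),
        reactions = list(R001 = list(substrates = "C001",
                                     products = "C002")))
    expect_true("3.6.3.29" %in% names(ref@ecToReactions))
    expect_false("3.6.3.29" %in% names(ref@ecToPathways))
    path <- tempfile(fileext = ".json")
    writeReference(ref, path)
    back <- loadReference(path)
    expect_identical(back@ecToReactions, ref@ecToReactions)
    expect_identical(back@ecToPathways, ref@ecToPathways)
    expect_identical(back@reactions, ref@reactions)
})

test_that("reference applies set semantics and survives empty input", {
    ref <- metabolicReference(
        ecToReactions = list("1.1.1.1" = c("R001", "R001", " r001 ")),
        reactions = list(R001 = list(substrates = "C1", products = "C2")))
    expect_identical(ref@ecToReactions[["1.1.1.1"]], "R001")

    empty <- tempfile(fileext = ".json")
    file.create(empty)
    e <- loadReference(empty)
    expect_length(e@ecToReactions, 0L)
    expect_length(e@reactions, 0L)

    expect_warning(
        metabolicReference(reactions = list(R9 = list(substrates = character(),
                                                      products = character()))),
        "no substrates and no products")
})

test_that("reference TSV link tables load equivalently to JSON", {
    tsv <- tempfile(fileext = ".tsv")
    writeLines(c(
        "link_type\tfrom\tto\trole",
        "ec_rn\t1.1.1.103\tR01975\t",
        "rn_cpd\tR01975\tC00188\tsubstrate",
        "rn_cpd\tR01975\tC03508\tproduct",
        "ec_path\t1.1.1.103\tmap00260\t",
        "cpd_path\tC00188\tmap00260\t",
        "name\tmap00260\tglycine, serine and threonine metabolism"), tsv)
    ref <- loadReference(tsv)
    expect_identical(ref@ecToReactions[["1.1.1.103"]], "R01975")
    expect_identical(ref@reactions[["R01975"]]$substrates, "C00188")
    expect_identical(ref@ecToPathways[["1.1.1.103"]], "MAP00260")
    expect_identical(ref@compoundToPathways[["C00188"]], "MAP00260")
    expect_match(ref@displayNames[["MAP00260"]], "threonine")
})

test_that("similarity table round-trips, floors at score 100, rejects bad rows", {
    set.seed(7)
    rec <- data.frame(
        gene_a = sprintf("aaa:g%02d", 1:10),
        gene_b = sprintf("bbb:h%02d", 1:10),
        sw_score = sample(100:900, 10),
        pct_identity = round(runif(10, 30, 95), 2),
        best_best = sample(c(TRUE, FALSE), 10, replace = TRUE),
        stringsAsFactors = FALSE)
    path <- tempfile(fileext = ".tsv")
    writeSimilarityTable(rec, path)
    back <- loadSimilarityTable(path)
    canon <- funcdisc:::.validateSimilarity(rec)
    expect_identical(back, canon)

    low <- rbind(rec, data.frame(gene_a = "aaa:g99", gene_b = "bbb:h99",
                                 sw_score = 99, pct_identity = 50,
                                 best_best = TRUE))
    expect_warning(kept <- funcdisc:::.validateSimilarity(low),
                   "score floor")
    expect_false("aaa:g99" %in% kept$gene_a)

    selfp <- rec; selfp$gene_b[1] <- selfp$gene_a[1]
    expect_warning(kept2 <- funcdisc:::.validateSimilarity(selfp),
                   "self-pair")
    expect_identical(nrow(kept2), 9L)

    bad <- rec; bad$pct_identity[3] <- 101
    expect_error(funcdisc:::.validateSimilarity(bad), "pct_identity")
})
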