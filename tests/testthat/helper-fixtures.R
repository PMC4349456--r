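# In-code fixture builders: tiny genomes and references constructed through
# the package's own readers so tests exercise the real I/O paths.

# Build a GenomeAnnotation by writing the tabular dialect to a temp file and
# loading it. `genes` is a data.frame with columns locus, start, end and
# optional replicon, topology, strand, product, ec (";"-joined string).
toyGenome <- function(genes, org = "tst", seqs = NULL) {
    n <- nrow(genes)
    tab <- data.frame(
        replicon_id = genes$replicon %||% rep("chr1", n),
        topology = genes$topology %||% rep("linear", n),
        locus_tag = genes$locus,
        start = genes$start,
        end = genes$end,
        strand = genes$strand %||% rep("+", n),
        product = genes$product %||% rep("", n),
        ec_numbers = genes$ec %||% rep("", n),
        stringsAsFactors = FALSE)
    path <- tempfile(fileext = ".tsv")
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    faa <- NULL
    if (!is.null(seqs)) {
        faa <- tempfile(fileext = ".faa")
        writeLines(paste0(">", names(seqs), "\n", unname(seqs)), faa)
    }
    loadGenome(path, faa, orgCode = org)
}

# evenly spaced coordinates for n genes
coordSeq <- function(n, width = 500L, gap = 100L) {
    start <- (seq_len(n) - 1L) * (width + gap) + 1L
    data.frame(start = start, end = start + width - 1L)
}

# neighborhood list over one genome: one window per anchor locus
toyNeighborhoods <- function(genome, anchors, n) {
    nbs <- lapply(anchors, function(a) extractNeighborhood(genome, a, n))
    names(nbs) <- anchors
    nbs
}

# minimal reference: each EC gets one reaction S -> P; optional pathway
# wiring maps ECs and their compounds to the named pathway
toyReference <- function(ecs, pathways = NULL) {
    e2r <- list(); rx <- list(); e2p <- list(); c2p <- list()
    for (i in seq_along(ecs)) {
        rn <- sprintf("R%03d", i)
        cp <- sprintf("C%03d", c(2L * i - 1L, 2L * i))
        e2r[[ecs[i]]] <- rn
        rx[[rn]] <- list(substrates = cp[1], products = cp[2])
        if (!is.null(pathways) && !is.na(pathways[i])) {
            e2p[[ecs[i]]] <- pathways[i]
            for (x in cp) c2p[[x]] <- pathways[i]
        }
    }
    metabolicReference(e2r, rx, e2p, c2p)
}
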