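#' @include AllClasses.R
NULL

# ids in the metabolic reference and similarity tables are case-insensitive;
# canonical form is uppercase with surrounding whitespace stripped
.normalizeId <- function(x) toupper(trimws(x))

# Shared validator/builder behind both annotation readers. `tab` is one row
# per CDS with columns replicon_id, topology, locus_tag, start, end, strand,
# product and a list-column ec (character vectors, possibly empty).
.buildGenomeAnnotation <- function(orgCode, tab, proteome) {
    if (anyDuplicated(tab$locus_tag)) {
        stop("duplicate locus_tag: ",
             paste(unique(tab$locus_tag[duplicated(tab$locus_tag)]),
                   collapse = ", "))
    }
    bad_start <- tab$start >= tab$end
    if (any(bad_start))
        stop("gene with start >= end: ",
             paste(tab$locus_tag[bad_start], collapse = ", "))
    # malformed EC strings are dropped, not fatal: annotation pipelines leave
    # all sorts of debris in eC_number fields
    tab$ec <- lapply(seq_len(nrow(tab)), function(i) {
        ec <- .normalizeId(tab$ec[[i]])
        ec <- ec[nzchar(ec)]
        bad <- !grepl(.EC_PATTERN, ec)
        if (any(bad)) {
            warning("gene ", tab$locus_tag[i], ": skipping malformed EC ",
                    paste(ec[bad], collapse = ", "), call. = FALSE)
        }
        sort(unique(ec[!bad]))
    })
    # canonical gene order: start coordinate within replicon (input row order
    # must not matter); ties broken by end then locus_tag
    ord <- order(tab$replicon_id, tab$start, tab$end, tab$locus_tag)
    tab <- tab[ord, , drop = FALSE]
    index <- as.integer(stats::ave(seq_len(nrow(tab)), tab$replicon_id,
                                   FUN = seq_along)) - 1L
    gene_id <- paste0(orgCode, ":", tab$locus_tag)
    gr <- GenomicRanges::GRanges(
        seqnames = tab$replicon_id,
        ranges = IRanges::IRanges(start = tab$start, end = tab$end),
        strand = tab$strand
    )
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        gene_id = gene_id,
        index = as.integer(index),
        product = as.character(tab$product),
        ec_numbers = IRanges::CharacterList(tab$ec)
    )
    reps <- unique(data.frame(replicon_id = tab$replicon_id,
                              topology = tab$topology,
                              stringsAsFactors = FALSE))
    reps <- reps[order(reps$replicon_id), , drop = FALSE]
    rownames(reps) <- NULL

    # match proteome sequences to genes by locus tag; keep unmatched genes
    # with an empty sequence so neighborhoods stay complete
    seqs <- Biostrings::AAStringSet(rep("", nrow(tab)))
    names(seqs) <- gene_id
    if (length(proteome)) {
        names(proteome) <- sub("\\s.*$", "", names(proteome))
        hit <- match(tab$locus_tag, names(proteome))
        found <- !is.na(hit)
        if (any(found)) seqs[found] <- proteome[hit[found]]
        missing <- tab$locus_tag[!found]
        if (length(missing)) {
            warning("no protein sequence for ", length(missing), " gene(s): ",
                    paste(utils::head(missing, 5), collapse = ", "),
                    if (length(missing) > 5) ", ..." else "", call. = FALSE)
        }
        orphan <- setdiff(names(proteome), tab$locus_tag)
        if (length(orphan)) {
            warning(length(orphan),
                    " proteome sequence(s) without an annotated gene ignored",
                    call. = FALSE)
        }
    }
    new("GenomeAnnotation", orgCode = orgCode, replicons = reps,
        genes = gr, proteome = seqs)
}

#' Load a genome annotation and its proteome
#'
#' Reads per-genome gene models from either GFF3 (CDS features with
#' \code{locus_tag}, optional \code{eC_number} and \code{product} attributes;
#' circular replicons flagged by \code{Is_circular=true} on a region feature)
#' or the package's tabular dialect (see Details), plus an optional protein
#' FASTA keyed by locus tag. Genes are ordered by start coordinate within
#' each replicon and assigned a 0-based \code{index}; input row order is
#' irrelevant.
#'
#' The tabular dialect is a TSV with header
#' \code{replicon_id topology locus_tag start end strand product ec_numbers},
#' EC numbers separated by \code{;}. It exists because EC annotation in wild
#' GFF3 is inconsistent; both readers share one validator.
#'
#' @param annotationPath path to a \code{.gff3}/\code{.gff} or \code{.tsv}
#'   file.
#' @param proteomePath optional FASTA of protein sequences named by locus
#'   tag; genes without a sequence are kept with an empty one (warning).
#' @param orgCode organism code used to form \code{org:locus} gene ids;
#'   defaults to the annotation file's base name.
#' @return a [GenomeAnnotation-class].
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   paste("chr1\tx\tCDS\t100\t400\t.\t+\t0",
#'         "ID=g1;locus_tag=g1;product=kinase;eC_number=2.7.1.39",
#'         sep = "\t")), gff)
#' loadGenome(gff, orgCode = "tst")
#' @export
loadGenome <- function(annotationPath, proteomePath = NULL, orgCode = NULL) {
    if (is.null(orgCode))
        orgCode <- tools::file_path_sans_ext(basename(annotationPath))
    proteome <- if (!is.null(proteomePath)) {
        Biostrings::readAAStringSet(proteomePath)
    } else {
        Biostrings::AAStringSet()
    }
    ext <- tolower(tools::file_ext(annotationPath))
    tab <- if (ext %in% c("gff", "gff3")) {
        .readGff3Genes(annotationPath)
    } else {
        .readGeneTsv(annotationPath)
    }
    if (nrow(tab) == 0L) {
        return(new("GenomeAnnotation", orgCode = orgCode,
                   replicons = data.frame(replicon_id = character(),
                                          topology = character()),
                   genes = GenomicRanges::GRanges(),
                   proteome = Biostrings::AAStringSet()))
    }
    .buildGenomeAnnotation(orgCode, tab, proteome)
}

.readGff3Genes <- function(path) {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    # replicon topology from region/chromosome features (Is_circular=true)
    circ <- character()
    if ("Is_circular" %in% names(mc)) {
        is_region <- as.character(mc$type) %in% c("region", "chromosome")
        flagged <- is_region & !is.na(mc$Is_circular) &
            tolower(as.character(mc$Is_circular)) == "true"
        circ <- unique(as.character(GenomicRanges::seqnames(gr))[flagged])
    }
    cds <- gr[as.character(mc$type) == "CDS"]
    if (length(cds) == 0L) {
        return(data.frame(replicon_id = character(), topology = character(),
                          locus_tag = character(), start = integer(),
                          end = integer(), strand = character(),
                          product = character()))
    }
    mc <- S4Vectors::mcols(cds)
    if (!"locus_tag" %in% names(mc))
        stop("GFF3 CDS features lack a locus_tag attribute")
    ec <- if ("eC_number" %in% names(mc)) {
        as.list(mc$eC_number)
    } else {
        rep(list(character()), length(cds))
    }
    ec <- lapply(ec, function(e) as.character(e[!is.na(e)]))
    prod <- if ("product" %in% names(mc)) as.character(mc$product) else ""
    prod[is.na(prod)] <- ""
    repl <- as.character(GenomicRanges::seqnames(cds))
    out <- data.frame(
        replicon_id = repl,
        topology = ifelse(repl %in% circ, "circular", "linear"),
        locus_tag = as.character(mc$locus_tag),
        start = GenomicRanges::start(cds),
        end = GenomicRanges::end(cds),
        strand = as.character(GenomicRanges::strand(cds)),
        product = prod,
        stringsAsFactors = FALSE
    )
    out$strand[!out$strand %in% c("+", "-")] <- "+"
    out$ec <- ec
    out
}

.readGeneTsv <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             quote = "", comment.char = "#",
                             stringsAsFactors = FALSE)
    need <- c("replicon_id", "topology", "locus_tag", "start", "end",
              "strand", "product", "ec_numbers")
    if (nrow(tab) == 0L && ncol(tab) == 0L) {
        tab <- data.frame(matrix(nrow = 0, ncol = length(need),
                                 dimnames = list(NULL, need)))
    }
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("gene TSV lacks column(s): ", paste(miss, collapse = ", "))
    tab$ec <- strsplit(ifelse(is.na(tab$ec_numbers), "", tab$ec_numbers), ";",
                       fixed = TRUE)
    tab$product[is.na(tab$product)] <- ""
    tab$start <- as.integer(tab$start)
    tab$end <- as.integer(tab$end)
    tab
}

#' Write a genome annotation in the tabular dialect
#'
#' Emits the TSV dialect [loadGenome()] reads (deterministic: genes in
#' index order, ECs sorted and \code{;}-joined) and, optionally, the proteome
#' FASTA. \code{writeGenome} then \code{loadGenome} is lossless.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param annotationPath output TSV path.
#' @param proteomePath optional output FASTA path.
#' @return invisibly, \code{annotationPath}.
#' @export
writeGenome <- function(genome, annotationPath, proteomePath = NULL) {
    g <- genome@genes
    top <- genome@replicons$topology[
        match(as.character(GenomicRanges::seqnames(g)),
              genome@replicons$replicon_id)]
    tab <- data.frame(
        replicon_id = as.character(GenomicRanges::seqnames(g)),
        topology = top,
        locus_tag = sub("^[^:]*:", "", g$gene_id),
        start = GenomicRanges::start(g),
        end = GenomicRanges::end(g),
        strand = as.character(GenomicRanges::strand(g)),
        product = g$product,
        ec_numbers = vapply(g$ec_numbers, function(e)
            paste(sort(e), collapse = ";"), character(1)),
        stringsAsFactors = FALSE
    )
    tab <- tab[order(tab$replicon_id, g$index), , drop = FALSE]
    utils::write.table(tab, annotationPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(proteomePath)) {
        seqs <- genome@proteome
        names(seqs) <- sub("^[^:]*:", "", names(seqs))
        Biostrings::writeXStringSet(seqs[Biostrings::width(seqs) > 0],
                                    proteomePath)
    }
    invisible(annotationPath)
}

#' Construct a MetabolicReference from link lists
#'
#' Normalizes all ids (uppercase, whitespace stripped) and applies set
#' semantics to duplicated links. Reactions with neither substrates nor
#' products are kept with a warning.
#'
#' @param ecToReactions named list, EC -> reaction ids.
#' @param reactions named list, reaction id -> list(substrates=, products=).
#' @param ecToPathways named list, EC -> pathway ids.
#' @param compoundToPathways named list, compound id -> pathway ids.
#' @param displayNames named character of display names.
#' @return a [MetabolicReference-class].
#' @export
metabolicReference <- function(ecToReactions = list(), reactions = list(),
                               ecToPathways = list(),
                               compoundToPathways = list(),
                               displayNames = character()) {
    normMap <- function(m) {
        if (!length(m)) return(stats::setNames(list(), character()))
        m <- lapply(m, function(v) sort(unique(.normalizeId(v))))
        names(m) <- .normalizeId(names(m))
        m[order(names(m))]
    }
    rx <- lapply(reactions, function(r) {
        list(substrates = sort(unique(.normalizeId(r$substrates))),
             products = sort(unique(.normalizeId(r$products))))
    })
    if (length(rx)) {
        names(rx) <- .normalizeId(names(reactions))
        rx <- rx[order(names(rx))]
        empty <- vapply(rx, function(r)
            !length(r$substrates) && !length(r$products), logical(1))
        if (any(empty)) {
            warning("reaction(s) with no substrates and no products: ",
                    paste(names(rx)[empty], collapse = ", "), call. = FALSE)
        }
    } else {
        rx <- stats::setNames(list(), character())
    }
    dn <- as.character(displayNames)
    names(dn) <- .normalizeId(names(displayNames))
    new("MetabolicReference",
        ecToReactions = normMap(ecToReactions),
        reactions = rx,
        ecToPathways = normMap(ecToPathways),
        compoundToPathways = normMap(compoundToPathways),
        displayNames = dn[order(names(dn))])
}

#' Load a metabolic reference
#'
#' Reads the EC/reaction/compound/pathway link tables from either a JSON
#' document (keys \code{ec_reactions}, \code{reactions}, \code{ec_pathways},
#' \code{compound_pathways}, \code{names}) or a 4-column TSV of links
#' (\code{link_type} in \code{ec_rn}, \code{rn_cpd}, \code{ec_path},
#' \code{cpd_path}, \code{name}; then \code{from}, \code{to}, \code{role} —
#' role is \code{substrate}/\code{product} for \code{rn_cpd} rows and empty
#' otherwise). An empty file yields an empty reference. ECs absent from the
#' pathway tables load cleanly: transporter ECs are often mapped to no
#' pathway at all.
#'
#' @param path JSON (\code{.json}) or TSV file.
#' @return a [MetabolicReference-class].
#' @seealso [writeReference()]
#' @export
loadReference <- function(path) {
    if (tolower(tools::file_ext(path)) == "json") {
        if (file.size(path) == 0L) return(metabolicReference())
        doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                                   simplifyDataFrame = FALSE)
        rx <- lapply(doc$reactions, function(r)
            list(substrates = unlist(r$substrates),
                 products = unlist(r$products)))
        return(metabolicReference(
            ecToReactions = lapply(doc$ec_reactions, unlist),
            reactions = rx,
            ecToPathways = lapply(doc$ec_pathways, unlist),
            compoundToPathways = lapply(doc$compound_pathways, unlist),
            displayNames = unlist(doc$names) %||% character()))
    }
    tab <- tryCatch(
        utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE),
        error = function(e) data.frame())
    if (!nrow(tab)) return(metabolicReference())
    need <- c("link_type", "from", "to")
    if (!all(need %in% names(tab)))
        stop("reference TSV lacks column(s): ",
             paste(setdiff(need, names(tab)), collapse = ", "))
    if (!"role" %in% names(tab)) tab$role <- ""
    pick <- function(type) tab[tab$link_type == type, , drop = FALSE]
    asMap <- function(d) {
        if (!nrow(d)) return(list())
        split(d$to, d$from)
    }
    rn <- pick("rn_cpd")
    rx_ids <- unique(c(rn$from, unlist(asMap(pick("ec_rn")))))
    rx <- lapply(rx_ids, function(r) {
        rows <- rn[rn$from == r, , drop = FALSE]
        list(substrates = rows$to[rows$role == "substrate"],
             products = rows$to[rows$role == "product"])
    })
    names(rx) <- rx_ids
    nm <- pick("name")
    metabolicReference(
        ecToReactions = asMap(pick("ec_rn")),
        reactions = rx,
        ecToPathways = asMap(pick("ec_path")),
        compoundToPathways = asMap(pick("cpd_path")),
        displayNames = stats::setNames(nm$to, nm$from))
}

#' Write a metabolic reference as JSON
#'
#' Deterministic output: sorted keys and sorted id vectors, so identical
#' references produce identical bytes. Round-trips through [loadReference()].
#'
#' @param ref a [MetabolicReference-class].
#' @param path output path (\code{.json}).
#' @return invisibly, \code{path}.
#' @export
writeReference <- function(ref, path) {
    doc <- list(
        ec_reactions = ref@ecToReactions,
        reactions = ref@reactions,
        ec_pathways = ref@ecToPathways,
        compound_pathways = ref@compoundToPathways,
        names = as.list(ref@displayNames)
    )
    jsonlite::write_json(doc, path, auto_unbox = FALSE, pretty = TRUE)
    invisible(path)
}

#' Read and write pairwise similarity tables
#'
#' The similarity table plays the role of a precomputed sequence-similarity
#' database: one row per unordered gene pair with the local-alignment score
#' (\code{sw_score}), percent identity over the alignment, and whether the
#' pair is a bidirectional best hit (\code{best_best}). Only pairs with
#' \code{sw_score >= 100} are stored, mirroring the score floor of such
#' databases; lower-scoring rows are dropped at load with a warning, and
#' self-pairs are rejected. Written tables are deterministic (canonical
#' \code{gene_a < gene_b} within a row, rows sorted).
#'
#' @param records \code{data.frame} with columns \code{gene_a},
#'   \code{gene_b}, \code{sw_score}, \code{pct_identity}, \code{best_best}.
#' @param path TSV file path.
#' @return \code{loadSimilarityTable}: the validated \code{data.frame};
#'   \code{writeSimilarityTable}: invisibly, \code{path}.
#' @export
writeSimilarityTable <- function(records, path) {
    records <- .validateSimilarity(records)
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeSimilarityTable
#' @export
loadSimilarityTable <- function(path) {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
    if (!nrow(tab)) return(.emptySimilarity())
    tab$best_best <- as.logical(tab$best_best)
    .validateSimilarity(tab)
}

.emptySimilarity <- function() {
    data.frame(gene_a = character(), gene_b = character(),
               sw_score = integer(), pct_identity = numeric(),
               best_best = logical(), stringsAsFactors = FALSE)
}

.validateSimilarity <- function(tab) {
    need <- c("gene_a", "gene_b", "sw_score", "pct_identity", "best_best")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("similarity table lacks column(s): ",
             paste(miss, collapse = ", "))
    tab <- tab[need]
    if (any(tab$pct_identity < 0 | tab$pct_identity > 100))
        stop("pct_identity outside [0, 100]")
    self <- tab$gene_a == tab$gene_b
    if (any(self)) {
        warning(sum(self), " self-pair(s) rejected", call. = FALSE)
        tab <- tab[!self, , drop = FALSE]
    }
    low <- tab$sw_score < 100
    if (any(low)) {
        warning(sum(low), " record(s) below the similarity score floor of ",
                "100 dropped", call. = FALSE)
        tab <- tab[!low, , drop = FALSE]
    }
    # canonical unordered-pair form, one row per pair
    flip <- tab$gene_a > tab$gene_b
    tmp <- tab$gene_a[flip]
    tab$gene_a[flip] <- tab$gene_b[flip]
    tab$gene_b[flip] <- tmp
    tab <- tab[!duplicated(tab[c("gene_a", "gene_b")]), , drop = FALSE]
    tab <- tab[order(tab$gene_a, tab$gene_b), , drop = FALSE]
    tab$sw_score <- as.integer(tab$sw_score)
    rownames(tab) <- NULL
    tab
}

#' Load a complete genome-context datastore from a directory
#'
#' Expects the layout written by [writePangenome()]: a \code{genomes/}
#' subdirectory with one annotation file per organism (\code{<org>.tsv},
#' \code{.gff3} or \code{.gff}) plus matching \code{<org>.faa} proteomes, a
#' \code{similarity.tsv} table and a \code{reference.json} metabolic
#' reference.
#'
#' @param dir datastore directory.
#' @return a list with elements \code{genomes} (named list of
#'   [GenomeAnnotation-class]), \code{similarity} (\code{data.frame}) and
#'   \code{reference} ([MetabolicReference-class]).
#' @export
loadDatastore <- function(dir) {
    gdir <- file.path(dir, "genomes")
    ann <- list.files(gdir, pattern = "\\.(tsv|gff3?|gff)$",
                      full.names = TRUE)
    if (!length(ann))
        stop("no genome annotations under ", gdir)
    genomes <- lapply(ann, function(p) {
        org <- tools::file_path_sans_ext(basename(p))
        faa <- file.path(gdir, paste0(org, ".faa"))
        loadGenome(p, if (file.exists(faa)) faa else NULL, orgCode = org)
    })
    names(genomes) <- vapply(genomes, orgCode, character(1))
    simPath <- file.path(dir, "similarity.tsv")
    refPath <- file.path(dir, "reference.json")
    list(
        genomes = genomes,
        similarity = if (file.exists(simPath)) loadSimilarityTable(simPath)
                     else .emptySimilarity(),
        reference = if (file.exists(refPath)) loadReference(refPath)
                    else metabolicReference()
    )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
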