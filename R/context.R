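#' @include AllClasses.R homology.R
NULL

#' Extract the gene neighborhood around an anchor gene
#'
#' Returns the window of genes whose along-replicon rank lies within
#' \code{nNeighbors} of the anchor's rank — position, not strand, defines
#' membership, since regulated clusters routinely mix strands. Windows
#' truncate at the ends of linear replicons; on circular replicons they wrap
#' around the origin, capped at the replicon size so no gene appears twice.
#'
#' @param genome a [GenomeAnnotation-class].
#' @param anchorGeneId gene id of the anchor (must exist in \code{genome}).
#' @param nNeighbors window half-width in genes (>= 0).
#' @return a [Neighborhood-class] with genes in along-window order.
#' @export
extractNeighborhood <- function(genome, anchorGeneId, nNeighbors) {
    stopifnot(nNeighbors >= 0)
    g <- genome@genes
    hit <- which(g$gene_id == anchorGeneId)
    if (length(hit) != 1L)
        stop("anchor gene not found: ", anchorGeneId)
    repl <- as.character(GenomicRanges::seqnames(g))[hit]
    onRep <- g[as.character(GenomicRanges::seqnames(g)) == repl]
    onRep <- onRep[order(onRep$index)]
    N <- length(onRep)
    i <- g$index[hit]
    circular <- genome@replicons$topology[
        genome@replicons$replicon_id == repl] == "circular"
    offs <- seq.int(i - nNeighbors, i + nNeighbors)
    idx <- if (circular) unique(offs %% N) else offs[offs >= 0 & offs < N]
    new("Neighborhood", anchorGeneId = anchorGeneId,
        genes = onRep[idx + 1L])
}

# unique anchor ids joined for the support column
.support <- function(ids) paste(sort(unique(ids)), collapse = ",")

.lookupNames <- function(ids, ref) {
    if (is.null(ref)) return(rep("", length(ids)))
    nm <- unname(ref@displayNames[ids])
    ifelse(is.na(nm), "", nm)
}

#' Rank enzymes by how many neighborhoods they occur in
#'
#' Frequency is per-neighborhood presence: an EC counts once per distinct
#' neighborhood containing at least one gene annotated with it, however many
#' copies that neighborhood holds — tandem duplications must not inflate
#' rank. Genes without EC annotation are ignored; an empty table is a legal
#' outcome.
#'
#' @param neighborhoods list of [Neighborhood-class].
#' @param ref optional [MetabolicReference-class], used only for display
#'   names.
#' @return \code{data.frame} with columns \code{ec}, \code{frequency},
#'   \code{name}, \code{support} (comma-joined anchor gene ids), sorted by
#'   frequency descending then EC.
#' @export
summarizeEnzymes <- function(neighborhoods, ref = NULL) {
    stopifnot(length(neighborhoods) >= 1L)
    occ <- do.call(rbind, lapply(neighborhoods, function(nb) {
        ecs <- unique(unlist(nb@genes$ec_numbers))
        if (!length(ecs)) return(NULL)
        data.frame(ec = ecs, anchor = nb@anchorGeneId,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(occ) || !nrow(occ)) {
        return(data.frame(ec = character(), frequency = integer(),
                          name = character(), support = character(),
                          stringsAsFactors = FALSE))
    }
    tab <- stats::aggregate(anchor ~ ec, data = occ,
                            FUN = function(a) .support(a))
    freq <- stats::aggregate(anchor ~ ec, data = occ, FUN = length)
    out <- data.frame(ec = tab$ec,
                      frequency = as.integer(freq$anchor),
                      name = .lookupNames(tab$ec, ref),
                      support = tab$anchor,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, out$ec), , drop = FALSE]
    rownames(out) <- NULL
    out
}

# compounds reachable from one EC through its reactions
.ecCompounds <- function(ec, ref) {
    rns <- ref@ecToReactions[[ec]]
    if (is.null(rns) || !length(rns)) return(character())
    unique(unlist(lapply(ref@reactions[rns], function(r)
        c(r$substrates, r$products))))
}

#' Rank reaction metabolites by how many neighborhoods imply them
#'
#' The compound universe is the union of substrates and products over all
#' reactions of the enzymes in the enzyme summary. A compound's frequency is
#' the number of distinct neighborhoods containing at least one gene whose
#' EC's reactions involve it — two enzymes sharing a compound in the same
#' neighborhood count that neighborhood once, not twice. An optional
#' exclusion list removes currency metabolites (water, ATP, ...) that would
#' otherwise top every table; see
#' \code{system.file("extdata", "currency_metabolites.txt", package =
#' "funcdisc")} for the shipped list (off by default).
#'
#' @param enzymeSummary output of [summarizeEnzymes()].
#' @param neighborhoods the same list of [Neighborhood-class] objects.
#' @param ref a [MetabolicReference-class].
#' @param exclude character vector of compound ids, or a path to a file
#'   with one id per line; excluded compounds are dropped from the table.
#' @return \code{data.frame} with columns \code{compound}, \code{frequency},
#'   \code{name}, \code{support}, sorted by frequency descending then id.
#' @export
summarizeMetabolites <- function(enzymeSummary, neighborhoods, ref,
                                 exclude = NULL) {
    if (length(exclude) == 1L && file.exists(exclude))
        exclude <- readLines(exclude)
    exclude <- .normalizeId(exclude %||% character())
    ecs <- enzymeSummary$ec
    noRxn <- ecs[vapply(ecs, function(e)
        is.null(ref@ecToReactions[[e]]) || !length(ref@ecToReactions[[e]]),
        logical(1))]
    if (length(noRxn))
        message("EC(s) with no reactions in the reference: ",
                paste(noRxn, collapse = ", "))
    cpdByEc <- lapply(stats::setNames(ecs, ecs), .ecCompounds, ref = ref)
    occ <- do.call(rbind, lapply(neighborhoods, function(nb) {
        nbEcs <- intersect(unique(unlist(nb@genes$ec_numbers)), ecs)
        cpds <- unique(unlist(cpdByEc[nbEcs]))
        cpds <- setdiff(cpds, exclude)
        if (!length(cpds)) return(NULL)
        data.frame(compound = cpds, anchor = nb@anchorGeneId,
                   stringsAsFactors = FALSE)
    }))
    if (is.null(occ) || !nrow(occ)) {
        return(data.frame(compound = character(), frequency = integer(),
                          name = character(), support = character(),
                          stringsAsFactors = FALSE))
    }
    supp <- stats::aggregate(anchor ~ compound, data = occ, FUN = .support)
    freq <- stats::aggregate(anchor ~ compound, data = occ, FUN = length)
    out <- data.frame(compound = supp$compound,
                      frequency = as.integer(freq$anchor),
                      name = .lookupNames(supp$compound, ref),
                      support = supp$anchor,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$frequency, out$compound), , drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Rank pathways by hits from mapped enzymes and metabolites
#'
#' Merges the two previous summaries: a pathway's hit count is the sum of
#' the frequencies of every summary EC and every summary compound mapped to
#' it (\code{scoreMode = "weighted"}, the default), or simply the number of
#' distinct mapped entities (\code{scoreMode = "distinct"}). Entities with
#' no pathway mapping contribute nothing; when nothing maps — transport
#' systems are the notorious case, their ECs often have no pathway at all —
#' the table is legitimately empty and downstream report rendering must
#' still work.
#'
#' @param enzymeSummary output of [summarizeEnzymes()].
#' @param metaboliteSummary output of [summarizeMetabolites()].
#' @param ref a [MetabolicReference-class].
#' @param scoreMode \code{"weighted"} or \code{"distinct"}.
#' @return \code{data.frame} with columns \code{pathway}, \code{hits},
#'   \code{name}, \code{support} (the mapped ECs and compounds), sorted by
#'   hits descending then id.
#' @export
summarizePathways <- function(enzymeSummary, metaboliteSummary, ref,
                              scoreMode = c("weighted", "distinct")) {
    scoreMode <- match.arg(scoreMode)
    links <- rbind(
        .pathwayLinks(enzymeSummary$ec, enzymeSummary$frequency,
                      ref@ecToPathways),
        .pathwayLinks(metaboliteSummary$compound,
                      metaboliteSummary$frequency, ref@compoundToPathways))
    if (is.null(links) || !nrow(links)) {
        return(data.frame(pathway = character(), hits = integer(),
                          name = character(), support = character(),
                          stringsAsFactors = FALSE))
    }
    hits <- if (scoreMode == "weighted") {
        stats::aggregate(freq ~ pathway, data = links, FUN = sum)
    } else {
        stats::aggregate(freq ~ pathway, data = links, FUN = length)
    }
    supp <- stats::aggregate(entity ~ pathway, data = links, FUN = .support)
    out <- data.frame(pathway = hits$pathway,
                      hits = as.integer(hits$freq),
                      name = .lookupNames(hits$pathway, ref),
                      support = supp$entity,
                      stringsAsFactors = FALSE)
    out <- out[order(-out$hits, out$pathway), , drop = FALSE]
    rownames(out) <- NULL
    out
}

.pathwayLinks <- function(entities, freqs, map) {
    if (!length(entities)) return(NULL)
    do.call(rbind, lapply(seq_along(entities), function(i) {
        p <- map[[entities[i]]]
        if (is.null(p) || !length(p)) return(NULL)
        data.frame(pathway = p, entity = entities[i], freq = freqs[i],
                   stringsAsFactors = FALSE)
    }))
}

#' Run the full neighborhood analysis for a query regulator
#'
#' Deterministic composition of the pipeline: select the query's
#' bidirectional-best-hit homologs from the similarity table
#' ([selectHomologs()]), extract each homolog's neighborhood in its own
#' genome ([extractNeighborhood()]), then compute the three
#' over-representation summaries. Identical inputs give identical results —
#' all ranking ties are broken lexicographically.
#'
#' @param query a [HomologQuery-class].
#' @param datastore list as returned by [loadDatastore()] or
#'   [generatePangenome()] (elements \code{genomes}, \code{similarity},
#'   \code{reference}).
#' @param scoreMode pathway scoring mode, see [summarizePathways()].
#' @param excludeCompounds optional currency-metabolite exclusion, see
#'   [summarizeMetabolites()].
#' @return a [NeighborhoodAnalysis-class].
#' @examples
#' pg <- generatePangenome(fixtureConfig(nGenomes = 4, genesPerGenome = 20,
#'                                       seed = 7))
#' res <- runAnalysis(homologQuery(pg$queryGeneId, nNeighbors = 5), pg)
#' pathwaySummary(res)[1, ]
#' @export
runAnalysis <- function(query, datastore,
                        scoreMode = c("weighted", "distinct"),
                        excludeCompounds = NULL) {
    scoreMode <- match.arg(scoreMode)
    ref <- datastore$reference
    byOrg <- function(gid) {
        org <- sub(":.*$", "", gid)
        g <- datastore$genomes[[org]]
        if (is.null(g))
            stop("no genome loaded for organism '", org, "' (gene ", gid, ")")
        g
    }
    qGenome <- byOrg(query@queryGeneId)
    if (!query@queryGeneId %in% qGenome@genes$gene_id)
        stop("query gene not found in datastore: ", query@queryGeneId)
    ids <- selectHomologs(query, datastore$similarity)
    nbs <- lapply(ids, function(gid)
        extractNeighborhood(byOrg(gid), gid, query@nNeighbors))
    names(nbs) <- ids
    enz <- summarizeEnzymes(nbs, ref)
    met <- summarizeMetabolites(enz, nbs, ref, exclude = excludeCompounds)
    pat <- summarizePathways(enz, met, ref, scoreMode = scoreMode)
    new("NeighborhoodAnalysis", query = query, homologs = ids,
        neighborhoods = nbs, enzymeSummary = enz, metaboliteSummary = met,
        pathwaySummary = pat, scoreMode = scoreMode)
}
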