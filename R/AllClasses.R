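#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges CharacterList
#' @importFrom Biostrings AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings AAStringSet
NULL

# EC numbers look like "1.1.1.103" or "3.6.3.-" (last field may be undetermined)
.EC_PATTERN <- "^[0-9]+\\.[0-9]+\\.[0-9]+\\.([0-9]+|-)$"

#' GenomeAnnotation: ordered gene models and proteome for one organism
#'
#' Holds the annotated genes of a single organism as a \link[GenomicRanges]{GRanges}
#' (one range per CDS, with \code{gene_id}, \code{index}, \code{product} and
#' \code{ec_numbers} metadata columns), a replicon table recording topology
#' (\code{linear} or \code{circular}), and the proteome as an
#' \link[Biostrings]{AAStringSet} named by \code{gene_id}.
#'
#' Gene identifiers follow the \code{org:locus} convention (a short organism
#' code, a colon, then the locus tag). The \code{index} column is the 0-based
#' rank of a gene along its replicon in start-coordinate order; neighborhood
#' windows are defined on this rank, not on base pairs.
#'
#' @slot orgCode short organism code (3-4 letters by convention).
#' @slot replicons \code{data.frame} with columns \code{replicon_id} and
#'   \code{topology}.
#' @slot genes \code{GRanges} of CDS features; seqnames are replicon ids.
#' @slot proteome \code{AAStringSet} keyed by \code{gene_id}; genes without a
#'   sequence carry a zero-length entry.
#'
#' @seealso [loadGenome()], [extractNeighborhood()]
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation",
    representation(
        orgCode = "character",
        replicons = "data.frame",
        genes = "GRanges",
        proteome = "AAStringSet"
    )
)

setValidity("GenomeAnnotation", function(object) {
    msg <- character()
    g <- object@genes
    if (length(object@orgCode) != 1L || !nzchar(object@orgCode))
        msg <- c(msg, "orgCode must be a single non-empty string")
    if (!all(c("replicon_id", "topology") %in% names(object@replicons)))
        msg <- c(msg, "replicons needs columns replicon_id, topology")
    if (!all(object@replicons$topology %in% c("linear", "circular")))
        msg <- c(msg, "replicon topology must be 'linear' or 'circular'")
    if (length(g) > 0L) {
        need <- c("gene_id", "index", "product", "ec_numbers")
        if (!all(need %in% names(S4Vectors::mcols(g)))) {
            msg <- c(msg, paste("genes needs mcols:", paste(need, collapse = ", ")))
        } else {
            if (anyDuplicated(g$gene_id))
                msg <- c(msg, "duplicate gene_id")
            ok_idx <- vapply(
                split(g$index, as.character(GenomicRanges::seqnames(g))),
                function(ix) identical(sort(ix), seq_along(ix) - 1L),
                logical(1)
            )
            if (!all(ok_idx))
                msg <- c(msg, "gene index must be 0..n-1 without gaps per replicon")
            ecs <- unlist(g$ec_numbers)
            if (length(ecs) && !all(grepl(.EC_PATTERN, ecs)))
                msg <- c(msg, "malformed EC number in ec_numbers")
            if (!all(as.character(GenomicRanges::seqnames(g)) %in%
                     object@replicons$replicon_id))
                msg <- c(msg, "gene on unknown replicon")
        }
    }
    if (length(object@proteome) &&
        !all(names(object@proteome) %in% g$gene_id))
        msg <- c(msg, "proteome entry without matching gene")
    if (length(msg)) msg else TRUE
})

#' MetabolicReference: local EC/reaction/compound/pathway link tables
#'
#' A self-contained stand-in for an online metabolic database: which reactions
#' an EC number catalyses, which compounds each reaction consumes and
#' produces, and which pathways ECs and compounds belong to. An EC may
#' legitimately be absent from the pathway map (transport systems often are),
#' in which case it contributes enzymes and metabolites to the analysis but no
#' pathway hits.
#'
#' @slot ecToReactions named list: EC -> character vector of reaction ids.
#' @slot reactions named list: reaction id -> list(substrates=, products=).
#' @slot ecToPathways named list: EC -> character vector of pathway ids.
#' @slot compoundToPathways named list: compound id -> pathway ids.
#' @slot displayNames named character: optional display names for any id.
#'
#' @seealso [loadReference()], [summarizeMetabolites()], [summarizePathways()]
#' @exportClass MetabolicReference
setClass("MetabolicReference",
    representation(
        ecToReactions = "list",
        reactions = "list",
        ecToPathways = "list",
        compoundToPathways = "list",
        displayNames = "character"
    ),
    prototype(
        ecToReactions = list(), reactions = list(), ecToPathways = list(),
        compoundToPathways = list(),
        displayNames = stats::setNames(character(), character())
    )
)

setValidity("MetabolicReference", function(object) {
    msg <- character()
    rn_ref <- unique(unlist(object@ecToReactions))
    if (length(rn_ref) && !all(rn_ref %in% names(object@reactions)))
        msg <- c(msg, "EC references a reaction absent from reactions")
    for (r in object@reactions) {
        if (!all(c("substrates", "products") %in% names(r))) {
            msg <- c(msg, "each reaction needs substrates and products")
            break
        }
    }
    ids <- c(
        names(object@ecToReactions), names(object@reactions),
        names(object@ecToPathways), names(object@compoundToPathways),
        unlist(object@ecToPathways), unlist(object@compoundToPathways)
    )
    if (length(ids) && !all(nzchar(ids)))
        msg <- c(msg, "empty id string")
    if (length(msg)) msg else TRUE
})

#' HomologQuery: parameters of a neighborhood analysis run
#'
#' Bundles the query gene and the three knobs of the analysis: how many
#' homologs to consider (at most one per genome), the amino-acid identity
#' cutoff (aa-IDc, percent) applied to the bidirectional best hits, and how
#' many genes up- and downstream of each homolog define its neighborhood.
#' Defaults (100 homologs, 40\% identity, 10 neighbors) follow common practice
#' for regulator-context analysis: a looser identity cutoff starts admitting
#' same-family regulators that are not functional homologs, a stricter one
#' discards true homologs and starves the cross-genome counts.
#'
#' @slot queryGeneId query gene id ("org:locus").
#' @slot nHomologs maximum number of homologs (the query is always added).
#' @slot aaIdc percent amino-acid identity cutoff, in (0, 100].
#' @slot nNeighbors genes kept on each side of the anchor.
#'
#' @seealso [selectHomologs()], [runAnalysis()]
#' @exportClass HomologQuery
setClass("HomologQuery",
    representation(
        queryGeneId = "character",
        nHomologs = "integer",
        aaIdc = "numeric",
        nNeighbors = "integer"
    )
)

setValidity("HomologQuery", function(object) {
    msg <- character()
    if (length(object@queryGeneId) != 1L || !nzchar(object@queryGeneId))
        msg <- c(msg, "queryGeneId must be a single non-empty string")
    if (object@nHomologs < 1L) msg <- c(msg, "nHomologs must be >= 1")
    if (!(object@aaIdc > 0 && object@aaIdc <= 100))
        msg <- c(msg, "aaIdc must be in (0, 100]")
    if (object@nNeighbors < 0L) msg <- c(msg, "nNeighbors must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Construct a HomologQuery
#'
#' @param queryGeneId query gene id, "org:locus".
#' @param nHomologs maximum homolog count (default 100).
#' @param aaIdc percent identity cutoff (default 40).
#' @param nNeighbors window half-width in genes (default 10).
#' @return a [HomologQuery-class] object.
#' @examples
#' homologQuery("bxe:B3018")
#' @export
homologQuery <- function(queryGeneId, nHomologs = 100L, aaIdc = 40,
                         nNeighbors = 10L) {
    new("HomologQuery",
        queryGeneId = as.character(queryGeneId),
        nHomologs = as.integer(nHomologs),
        aaIdc = as.numeric(aaIdc),
        nNeighbors = as.integer(nNeighbors))
}

#' Neighborhood: the gene window around one homolog
#'
#' An ordered window of at most \code{2 * nNeighbors + 1} genes centred on an
#' anchor gene, in along-replicon order. Windows truncate at the ends of
#' linear replicons and wrap around circular ones without ever listing a gene
#' twice.
#'
#' @slot anchorGeneId the anchor's gene id.
#' @slot genes \code{GRanges} of the window, ordered by window position.
#'
#' @seealso [extractNeighborhood()]
#' @exportClass Neighborhood
setClass("Neighborhood",
    representation(anchorGeneId = "character", genes = "GRanges")
)

setValidity("Neighborhood", function(object) {
    if (!(object@anchorGeneId %in% object@genes$gene_id))
        return("anchor gene missing from window")
    TRUE
})

#' NeighborhoodAnalysis: homologs, neighborhoods and the three summaries
#'
#' The result of a full run: the ordered homolog list (query first), one
#' [Neighborhood-class] per homolog, and the three ranked over-representation
#' tables — enzymes (EC numbers) by the number of distinct neighborhoods they
#' occur in, metabolites (reaction substrates/products of those enzymes)
#' likewise, and pathways by summed hits over their mapped enzymes and
#' metabolites.
#'
#' @slot query the [HomologQuery-class] that produced the result.
#' @slot homologs character vector of gene ids, query first.
#' @slot neighborhoods named list of [Neighborhood-class], parallel to
#'   \code{homologs}.
#' @slot enzymeSummary \code{data.frame}: \code{ec}, \code{frequency},
#'   \code{name}, \code{support}.
#' @slot metaboliteSummary \code{data.frame}: \code{compound},
#'   \code{frequency}, \code{name}, \code{support}.
#' @slot pathwaySummary \code{data.frame}: \code{pathway}, \code{hits},
#'   \code{name}, \code{support}.
#' @slot scoreMode \code{"weighted"} or \code{"distinct"} pathway scoring.
#'
#' @seealso [runAnalysis()], [renderHtml()], [renderJson()]
#' @exportClass NeighborhoodAnalysis
setClass("NeighborhoodAnalysis",
    representation(
        query = "HomologQuery",
        homologs = "character",
        neighborhoods = "list",
        enzymeSummary = "data.frame",
        metaboliteSummary = "data.frame",
        pathwaySummary = "data.frame",
        scoreMode = "character"
    )
)

setValidity("NeighborhoodAnalysis", function(object) {
    msg <- character()
    if (!identical(names(object@neighborhoods), object@homologs))
        msg <- c(msg, "neighborhoods must be named by and parallel to homologs")
    if (!object@scoreMode %in% c("weighted", "distinct"))
        msg <- c(msg, "scoreMode must be 'weighted' or 'distinct'")
    if (nrow(object@enzymeSummary) &&
        any(object@enzymeSummary$frequency > length(object@neighborhoods)))
        msg <- c(msg, "enzyme frequency exceeds neighborhood count")
    if (length(msg)) msg else TRUE
})

#' HillFit: a fitted Hill binding model
#'
#' Result of nonlinear least-squares fitting of the saturation binding model
#' \deqn{\Delta A = \Delta A_T \, E^H / (K_d^H + E^H)}
#' to an anisotropy titration, where \eqn{E} is total protein concentration,
#' \eqn{K_d} the dissociation constant (same unit as \eqn{E}), \eqn{H} the
#' Hill coefficient and \eqn{\Delta A_T} the total anisotropy change.
#' Concentration units are carried as a tag and never converted.
#'
#' @slot estimates named numeric: \code{kd}, \code{h}, \code{deltaAT}.
#' @slot se named numeric standard errors (NA when unavailable).
#' @slot residualNorm residual sum of squares at the optimum.
#' @slot converged logical; FALSE flags a failed fit (estimates then hold the
#'   initial values).
#' @slot unit concentration unit tag of \code{E} and \code{kd} (e.g. "nM").
#' @slot data the titration points the fit used (columns \code{E},
#'   \code{delta_A}).
#'
#' @seealso [fitHill()], [hillModel()]
#' @exportClass HillFit
setClass("HillFit",
    representation(
        estimates = "numeric",
        se = "numeric",
        residualNorm = "numeric",
        converged = "logical",
        unit = "character",
        data = "data.frame"
    )
)

setValidity("HillFit", function(object) {
    msg <- character()
    if (!identical(names(object@estimates), c("kd", "h", "deltaAT")))
        msg <- c(msg, "estimates must be named kd, h, deltaAT")
    if (object@converged &&
        (object@estimates[["kd"]] <= 0 || object@estimates[["deltaAT"]] <= 0))
        msg <- c(msg, "converged fit requires kd > 0 and deltaAT > 0")
    if (length(msg)) msg else TRUE
})

#' FixtureConfig: parameters of the synthetic pangenome generator
#'
#' Describes the pangenome the generator emits: \code{nGenomes} single-replicon
#' (circular by default) genomes of \code{genesPerGenome} genes, each carrying
#' one regulator homolog. With probability \code{conservationProb} per genome
#' the planted cluster of \code{clusterSize} enzyme genes (all mapped to
#' \code{plantedPathwayId}) sits immediately beside the regulator — its
#' internal order shuffled with probability \code{rearrangementRate};
#' otherwise each cluster gene is deleted with probability \code{indelRate} or
#' relocated to a uniformly random position. \code{decoyEcCount} unrelated
#' enzyme genes per genome, each mapped to its own decoy pathway, are placed
#' uniformly at random and provide the background the planted signal must
#' beat.
#'
#' @slot nGenomes number of genomes.
#' @slot genesPerGenome genes per genome.
#' @slot clusterSize genes in the planted cluster.
#' @slot conservationProb per-genome probability the cluster is intact beside
#'   the regulator homolog.
#' @slot rearrangementRate probability the conserved cluster's internal gene
#'   order is shuffled.
#' @slot indelRate per-gene deletion probability when the cluster is not
#'   conserved.
#' @slot plantedPathwayId pathway id the cluster ECs map to.
#' @slot decoyEcCount number of decoy enzyme genes per genome.
#' @slot circular logical; circular replicons exercise window wraparound.
#' @slot seed integer RNG seed; identical seeds give byte-identical output.
#'
#' @seealso [fixtureConfig()], [generatePangenome()]
#' @exportClass FixtureConfig
setClass("FixtureConfig",
    representation(
        nGenomes = "integer",
        genesPerGenome = "integer",
        clusterSize = "integer",
        conservationProb = "numeric",
        rearrangementRate = "numeric",
        indelRate = "numeric",
        plantedPathwayId = "character",
        decoyEcCount = "integer",
        circular = "logical",
        seed = "integer"
    )
)

setValidity("FixtureConfig", function(object) {
    msg <- character()
    probs <- c(object@conservationProb, object@rearrangementRate,
               object@indelRate)
    if (any(probs < 0 | probs > 1))
        msg <- c(msg, "probabilities must be in [0, 1]")
    if (object@clusterSize >= object@genesPerGenome)
        msg <- c(msg, "clusterSize must be smaller than genesPerGenome")
    if (1L + object@clusterSize + object@decoyEcCount >
        object@genesPerGenome)
        msg <- c(msg, paste("genesPerGenome must fit the regulator,",
                            "clusterSize cluster genes and decoyEcCount",
                            "decoys"))
    if (object@nGenomes < 1L) msg <- c(msg, "nGenomes must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a FixtureConfig
#'
#' Defaults describe a 20-genome pangenome of 60-gene circular replicons with
#' a 4-gene planted cluster conserved in 80\% of genomes, 10\% rearrangement
#' and deletion rates, and 8 decoy enzyme genes per genome.
#'
#' @param nGenomes,genesPerGenome,clusterSize,conservationProb pangenome shape
#'   (see [FixtureConfig-class]).
#' @param rearrangementRate,indelRate perturbation rates.
#' @param plantedPathwayId,decoyEcCount planted signal and background.
#' @param circular replicon topology.
#' @param seed RNG seed.
#' @return a [FixtureConfig-class] object.
#' @examples
#' fixtureConfig(nGenomes = 5, seed = 42)
#' @export
fixtureConfig <- function(nGenomes = 20L, genesPerGenome = 60L,
                          clusterSize = 4L, conservationProb = 0.8,
                          rearrangementRate = 0.1, indelRate = 0.1,
                          plantedPathwayId = "PATH00260",
                          decoyEcCount = 8L, circular = TRUE, seed = 1L) {
    new("FixtureConfig",
        nGenomes = as.integer(nGenomes),
        genesPerGenome = as.integer(genesPerGenome),
        clusterSize = as.integer(clusterSize),
        conservationProb = as.numeric(conservationProb),
        rearrangementRate = as.numeric(rearrangementRate),
        indelRate = as.numeric(indelRate),
        plantedPathwayId = as.character(plantedPathwayId),
        decoyEcCount = as.integer(decoyEcCount),
        circular = isTRUE(circular),
        seed = as.integer(seed))
}
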