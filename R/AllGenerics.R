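#' @include AllClasses.R
NULL

#' Accessors for funcdisc classes
#'
#' Small accessor generics: \code{orgCode}, \code{replicons}, \code{genes} and
#' \code{proteome} read the slots of a [GenomeAnnotation-class];
#' \code{anchorGene} the anchor of a [Neighborhood-class]; \code{homologs},
#' \code{neighborhoods}, \code{enzymeSummary}, \code{metaboliteSummary} and
#' \code{pathwaySummary} the parts of a [NeighborhoodAnalysis-class].
#'
#' @param x an object of the documented class.
#' @return the slot value; summaries are \code{data.frame}s sorted in report
#'   order (rank 1 first).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("orgCode", function(x) standardGeneric("orgCode"))
#' @rdname accessors
#' @export
setGeneric("replicons", function(x) standardGeneric("replicons"))
#' @rdname accessors
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))
#' @rdname accessors
#' @export
setGeneric("proteome", function(x) standardGeneric("proteome"))
#' @rdname accessors
#' @export
setGeneric("anchorGene", function(x) standardGeneric("anchorGene"))
#' @rdname accessors
#' @export
setGeneric("homologs", function(x) standardGeneric("homologs"))
#' @rdname accessors
#' @export
setGeneric("neighborhoods", function(x) standardGeneric("neighborhoods"))
#' @rdname accessors
#' @export
setGeneric("enzymeSummary", function(x) standardGeneric("enzymeSummary"))
#' @rdname accessors
#' @export
setGeneric("metaboliteSummary",
           function(x) standardGeneric("metaboliteSummary"))
#' @rdname accessors
#' @export
setGeneric("pathwaySummary", function(x) standardGeneric("pathwaySummary"))

#' @rdname accessors
setMethod("orgCode", "GenomeAnnotation", function(x) x@orgCode)
#' @rdname accessors
setMethod("replicons", "GenomeAnnotation", function(x) x@replicons)
#' @rdname accessors
setMethod("genes", "GenomeAnnotation", function(x) x@genes)
#' @rdname accessors
setMethod("proteome", "GenomeAnnotation", function(x) x@proteome)
#' @rdname accessors
setMethod("genes", "Neighborhood", function(x) x@genes)
#' @rdname accessors
setMethod("anchorGene", "Neighborhood", function(x) x@anchorGeneId)
#' @rdname accessors
setMethod("homologs", "NeighborhoodAnalysis", function(x) x@homologs)
#' @rdname accessors
setMethod("neighborhoods", "NeighborhoodAnalysis", function(x) x@neighborhoods)
#' @rdname accessors
setMethod("enzymeSummary", "NeighborhoodAnalysis", function(x) x@enzymeSummary)
#' @rdname accessors
setMethod("metaboliteSummary", "NeighborhoodAnalysis",
          function(x) x@metaboliteSummary)
#' @rdname accessors
setMethod("pathwaySummary", "NeighborhoodAnalysis",
          function(x) x@pathwaySummary)

#' @describeIn accessors coefficients of a Hill fit (kd, h, deltaAT).
#' @param object a [HillFit-class].
#' @param ... ignored.
#' @importFrom stats coef
#' @exportMethod coef
setMethod("coef", "HillFit", function(object, ...) object@estimates)

setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation '", object@orgCode, "': ",
        length(object@genes), " genes on ",
        nrow(object@replicons), " replicon(s)\n", sep = "")
    n_ec <- sum(lengths(object@genes$ec_numbers) > 0)
    cat("  EC-annotated genes: ", n_ec,
        "; proteome sequences: ", sum(Biostrings::width(object@proteome) > 0),
        "\n", sep = "")
})

setMethod("show", "MetabolicReference", function(object) {
    cat("MetabolicReference: ", length(object@ecToReactions), " ECs, ",
        length(object@reactions), " reactions, ",
        length(unique(unlist(object@ecToPathways))), " pathways\n", sep = "")
})

setMethod("show", "HomologQuery", function(object) {
    cat("HomologQuery: ", object@queryGeneId,
        " (nHomologs=", object@nHomologs,
        ", aaIdc=", object@aaIdc,
        "%, nNeighbors=", object@nNeighbors, ")\n", sep = "")
})

setMethod("show", "Neighborhood", function(object) {
    cat("Neighborhood of ", object@anchorGeneId, ": ",
        length(object@genes), " genes\n", sep = "")
})

setMethod("show", "NeighborhoodAnalysis", function(object) {
    cat("NeighborhoodAnalysis for ", object@query@queryGeneId, "\n",
        "  homologs: ", length(object@homologs),
        "  enzymes: ", nrow(object@enzymeSummary),
        "  metabolites: ", nrow(object@metaboliteSummary),
        "  pathways: ", nrow(object@pathwaySummary), "\n", sep = "")
    if (nrow(object@pathwaySummary)) {
        top <- object@pathwaySummary[1L, ]
        cat("  top pathway: ", top$pathway, " (hits=", top$hits, ")\n",
            sep = "")
    }
})

setMethod("show", "HillFit", function(object) {
    est <- object@estimates
    cat("HillFit (", if (object@converged) "converged" else "NOT converged",
        "): Kd = ", signif(est[["kd"]], 4), " ", object@unit,
        ", H = ", signif(est[["h"]], 3),
        ", deltaA_T = ", signif(est[["deltaAT"]], 3),
        ", RSS = ", signif(object@residualNorm, 3), "\n", sep = "")
})

setMethod("show", "FixtureConfig", function(object) {
    cat("FixtureConfig: ", object@nGenomes, " genomes x ",
        object@genesPerGenome, " genes; cluster ", object@clusterSize,
        " (conservation ", object@conservationProb, "), ",
        object@decoyEcCount, " decoy ECs, seed ", object@seed, "\n", sep = "")
})
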