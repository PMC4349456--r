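#' @include AllClasses.R datastore.R homology.R
NULL

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.randomProtein <- function(len) {
    paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

# point-substitution descendant of an ancestor sequence; subProb is the
# per-site probability of replacement by a different residue
.mutateProtein <- function(seq, subProb) {
    chars <- strsplit(seq, "")[[1]]
    hit <- stats::runif(length(chars)) < subProb
    if (any(hit)) {
        chars[hit] <- vapply(chars[hit], function(a)
            sample(setdiff(.AA20, a), 1L), character(1))
    }
    paste(chars, collapse = "")
}

#' Generate a seeded synthetic pangenome with a planted gene cluster
#'
#' Emits a complete in-memory datastore emulating a multi-genome collection
#' around a transcriptional regulator: every genome carries one regulator
#' homolog (an ortholog family descended from a common ancestor by point
#' substitution at 2\% per site, keeping within-family identity around
#' 95\%, above any practical identity cutoff), a planted cluster of
#' \code{clusterSize} enzyme genes whose ECs all map to
#' \code{plantedPathwayId}, and \code{decoyEcCount} decoy enzyme genes —
#' independent random sequences, pairwise identity far below 30\% — each
#' mapped to its own decoy pathway and placed uniformly at random. Per
#' genome, with probability \code{conservationProb} the cluster sits intact
#' beside the regulator (internal order shuffled with probability
#' \code{rearrangementRate}); otherwise each cluster gene is deleted with
#' probability \code{indelRate} or relocated to a uniformly random slot,
#' where it behaves exactly like a decoy. Remaining slots are filled with
#' unannotated random genes.
#'
#' The similarity table is built by aligning all within-family pairs
#' ([smithWaterman()] scoring) and keeping records at or above the score
#' floor, mirroring a precomputed similarity database: cross-family pairs
#' are unrelated random proteins whose local scores sit far below the floor
#' of 100, so restricting alignment to families loses nothing (verified
#' against a full [bestBestHits()] cross-product in the test suite).
#'
#' Output is fully deterministic given \code{cfg@seed}.
#'
#' @param cfg a [fixtureConfig()].
#' @return a list with elements \code{genomes} (named list of
#'   [GenomeAnnotation-class]), \code{similarity}, \code{reference},
#'   \code{queryGeneId} (the regulator gene of the first genome),
#'   \code{trGeneIds}, \code{clusterEcs}, \code{decoyEcs} and
#'   \code{plantedPathwayId}.
#' @examples
#' pg <- generatePangenome(fixtureConfig(nGenomes = 3, genesPerGenome = 15,
#'                                       seed = 11))
#' names(pg$genomes)
#' @export
generatePangenome <- function(cfg) {
    validObject(cfg)
    set.seed(cfg@seed)
    nG <- cfg@nGenomes
    G <- cfg@genesPerGenome
    K <- cfg@clusterSize
    orgs <- sprintf("sp%02d", seq_len(nG))
    planted <- .normalizeId(cfg@plantedPathwayId)

    clusterEcs <- sprintf("1.1.1.%d", 100 + seq_len(K))
    decoyEcs <- sprintf("2.7.1.%d", 10 + seq_len(cfg@decoyEcCount))
    reference <- .fixtureReference(clusterEcs, decoyEcs, planted)

    # family ancestors: regulator + one per cluster enzyme
    trAnc <- .randomProtein(150L)
    clAnc <- vapply(seq_len(K), function(i)
        .randomProtein(sample(110:160, 1L)), character(1))

    famSeqs <- c(list(TR = character()),
                 stats::setNames(rep(list(character()), K),
                                 paste0("CL", seq_len(K))))
    genomes <- vector("list", nG)
    trGeneIds <- character(nG)

    for (gi in seq_len(nG)) {
        org <- orgs[gi]
        slotGene <- vector("list", G)  # slot -> gene descriptor
        free <- rep(TRUE, G)
        takeRandom <- function() {
            open <- which(free)
            s <- open[sample.int(length(open), 1L)]
            free[s] <<- FALSE
            s
        }
        trSlot <- takeRandom()
        trSeq <- .mutateProtein(trAnc, 0.02)
        slotGene[[trSlot]] <- list(
            locus = "reg0001", product = "transcriptional regulator",
            ec = character(), seq = trSeq, family = "TR")
        conserved <- stats::runif(1) < cfg@conservationProb
        clOrder <- seq_len(K)
        if (conserved && stats::runif(1) < cfg@rearrangementRate)
            clOrder <- sample(clOrder)
        for (ci in seq_len(K)) {
            if (conserved) {
                # intact cluster immediately downstream of the regulator
                s <- (trSlot - 1L + which(clOrder == ci)) %% G + 1L
                if (!free[s]) s <- takeRandom() else free[s] <- FALSE
            } else {
                if (stats::runif(1) < cfg@indelRate) next  # deleted
                s <- takeRandom()
            }
            slotGene[[s]] <- list(
                locus = sprintf("clu%04d", ci),
                product = sprintf("planted cluster enzyme %d", ci),
                ec = clusterEcs[ci],
                seq = .mutateProtein(clAnc[ci], 0.02),
                family = paste0("CL", ci))
        }
        for (di in seq_len(cfg@decoyEcCount)) {
            s <- takeRandom()
            slotGene[[s]] <- list(
                locus = sprintf("dec%04d", di),
                product = sprintf("decoy enzyme %d", di),
                ec = decoyEcs[di],
                seq = .randomProtein(120L), family = NA_character_)
        }
        for (s in which(vapply(slotGene, is.null, logical(1)))) {
            slotGene[[s]] <- list(
                locus = sprintf("fil%04d", s),
                product = "hypothetical protein",
                ec = character(), seq = .randomProtein(80L),
                family = NA_character_)
        }

        starts <- (seq_len(G) - 1L) * 1200L + 1L
        tab <- data.frame(
            replicon_id = paste0(org, "_chr"),
            topology = if (cfg@circular) "circular" else "linear",
            locus_tag = vapply(slotGene, `[[`, character(1), "locus"),
            start = starts,
            end = starts + 3L * vapply(slotGene, function(x)
                nchar(x$seq), integer(1)) + 2L,
            strand = sample(c("+", "-"), G, replace = TRUE),
            product = vapply(slotGene, `[[`, character(1), "product"),
            stringsAsFactors = FALSE)
        tab$ec <- lapply(slotGene, `[[`, "ec")
        prot <- Biostrings::AAStringSet(vapply(slotGene, `[[`,
                                               character(1), "seq"))
        names(prot) <- tab$locus_tag
        genomes[[gi]] <- .buildGenomeAnnotation(org, tab, prot)
        trGeneIds[gi] <- paste0(org, ":reg0001")

        for (s in seq_len(G)) {
            fam <- slotGene[[s]]$family
            if (!is.na(fam)) {
                famSeqs[[fam]][paste0(org, ":", slotGene[[s]]$locus)] <-
                    slotGene[[s]]$seq
            }
        }
    }
    names(genomes) <- orgs

    list(genomes = genomes,
         similarity = .familySimilarity(famSeqs),
         reference = reference,
         queryGeneId = trGeneIds[1L],
         trGeneIds = trGeneIds,
         clusterEcs = clusterEcs,
         decoyEcs = decoyEcs,
         plantedPathwayId = planted)
}

# EC -> reaction -> compounds -> pathway wiring: each planted EC gets one
# reaction (one substrate, one product), all mapped to the planted pathway;
# each decoy EC mirrors that onto its own decoy pathway
.fixtureReference <- function(clusterEcs, decoyEcs, plantedPathwayId) {
    ecToReactions <- list(); reactions <- list()
    ecToPathways <- list(); compoundToPathways <- list()
    displayNames <- c(stats::setNames("planted pathway", plantedPathwayId))
    wire <- function(ec, rn, cpds, path) {
        ecToReactions[[ec]] <<- rn
        reactions[[rn]] <<- list(substrates = cpds[1], products = cpds[2])
        ecToPathways[[ec]] <<- path
        for (cp in cpds) {
            compoundToPathways[[cp]] <<-
                unique(c(compoundToPathways[[cp]], path))
        }
    }
    for (i in seq_along(clusterEcs)) {
        wire(clusterEcs[i], sprintf("RP%04d", i),
             sprintf("CP%04d", c(2L * i - 1L, 2L * i)), plantedPathwayId)
    }
    for (j in seq_along(decoyEcs)) {
        path <- sprintf("DPATH%03d", j)
        displayNames[path] <- sprintf("decoy pathway %d", j)
        wire(decoyEcs[j], sprintf("RD%04d", j),
             sprintf("CD%04d", c(2L * j - 1L, 2L * j)), path)
    }
    metabolicReference(ecToReactions, reactions, ecToPathways,
                       compoundToPathways, displayNames)
}

# all within-family pairs, aligned and recorded like a precomputed
# similarity database; every family member is one per genome, so within a
# genome pair the family partners are each other's best hit
.familySimilarity <- function(famSeqs, scoring = alignmentScoring()) {
    out <- list()
    for (fam in names(famSeqs)) {
        seqs <- famSeqs[[fam]]
        if (length(seqs) < 2L) next
        set <- Biostrings::AAStringSet(seqs)
        for (i in seq_len(length(set) - 1L)) {
            rest <- set[(i + 1L):length(set)]
            aln <- Biostrings::pairwiseAlignment(
                rest, set[[i]], type = "local",
                substitutionMatrix = scoring$matrix,
                gapOpening = scoring$gapOpen,
                gapExtension = scoring$gapExtend)
            alen <- Biostrings::nchar(aln)  # alignment length, gap columns included
            sc <- Biostrings::score(aln)
            keep <- sc >= scoring$swFloor
            if (!any(keep)) next
            out[[length(out) + 1L]] <- data.frame(
                gene_a = names(set)[i],
                gene_b = names(rest)[keep],
                sw_score = as.integer(round(sc[keep])),
                pct_identity = 100 * Biostrings::nmatch(aln)[keep] /
                    alen[keep],
                best_best = TRUE,
                stringsAsFactors = FALSE)
        }
    }
    if (!length(out)) return(.emptySimilarity())
    .validateSimilarity(do.call(rbind, out))
}

#' Write a generated pangenome to a datastore directory
#'
#' Emits exactly the on-disk layout [loadDatastore()] reads: per-genome
#' annotation TSVs and proteome FASTAs under \code{genomes/}, the
#' similarity table as \code{similarity.tsv} and the metabolic reference as
#' \code{reference.json}. All files are deterministic.
#'
#' @param pg a pangenome from [generatePangenome()].
#' @param dir output directory (created if needed).
#' @return invisibly, \code{dir}.
#' @export
writePangenome <- function(pg, dir) {
    gdir <- file.path(dir, "genomes")
    dir.create(gdir, recursive = TRUE, showWarnings = FALSE)
    for (org in names(pg$genomes)) {
        writeGenome(pg$genomes[[org]],
                    file.path(gdir, paste0(org, ".tsv")),
                    file.path(gdir, paste0(org, ".faa")))
    }
    writeSimilarityTable(pg$similarity, file.path(dir, "similarity.tsv"))
    writeReference(pg$reference, file.path(dir, "reference.json"))
    invisible(dir)
}
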