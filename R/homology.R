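#' @include AllClasses.R
NULL

#' SWAlignment: one local alignment
#'
#' The optimal Smith-Waterman local alignment of two protein sequences under
#' affine gap costs (a gap of length L costs \code{gapOpen + L * gapExtend}).
#' Percent identity is identical columns divided by full alignment length,
#' gap columns included in the denominator (the BLAST convention).
#'
#' @slot score alignment score.
#' @slot alignedA,alignedB gapped alignment strings (equal length).
#' @slot pctIdentity percent identity over the alignment.
#' @slot startA,endA,startB,endB 1-based aligned subsequence bounds.
#'
#' @seealso [smithWaterman()]
#' @exportClass SWAlignment
setClass("SWAlignment",
    representation(
        score = "numeric",
        alignedA = "character", alignedB = "character",
        pctIdentity = "numeric",
        startA = "integer", endA = "integer",
        startB = "integer", endB = "integer"
    )
)

setValidity("SWAlignment", function(object) {
    if (nchar(object@alignedA) != nchar(object@alignedB))
        return("aligned strings differ in length")
    TRUE
})

setMethod("show", "SWAlignment", function(object) {
    cat("SWAlignment: score ", object@score,
        ", identity ", round(object@pctIdentity, 1), "%\n",
        "  A [", object@startA, "-", object@endA, "] ",
        object@alignedA, "\n",
        "  B [", object@startB, "-", object@endB, "] ",
        object@alignedB, "\n", sep = "")
})

#' Alignment scoring parameters
#'
#' Bundles the substitution matrix, affine gap costs and the score floor
#' below which pairwise similarities are not recorded. The matrix may be
#' given as the name of a matrix shipped with Biostrings (\code{"BLOSUM62"},
#' \code{"BLOSUM50"}, \code{"PAM250"}, ...), a path to an NCBI-format matrix
#' text file, or a numeric matrix with residue dimnames.
#'
#' @param matrix substitution matrix (name, file path, or matrix).
#' @param gapOpen,gapExtend affine gap costs (positive penalties); a gap of
#'   length L costs \code{gapOpen + L * gapExtend}.
#' @param swFloor minimum score for a similarity record to be kept.
#' @return a list with elements \code{matrix}, \code{gapOpen},
#'   \code{gapExtend}, \code{swFloor}.
#' @examples
#' sc <- alignmentScoring()
#' sc$matrix["A", "A"]
#' @export
alignmentScoring <- function(matrix = "BLOSUM62", gapOpen = 11,
                             gapExtend = 1, swFloor = 100) {
    if (is.character(matrix) && length(matrix) == 1L) {
        if (file.exists(matrix)) {
            matrix <- readSubstitutionMatrix(matrix)
        } else {
            env <- new.env()
            utils::data(list = matrix, package = "Biostrings", envir = env)
            matrix <- get(matrix, envir = env)
        }
    }
    stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
              identical(rownames(matrix), colnames(matrix)),
              gapOpen >= 0, gapExtend >= 0)
    list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend,
         swFloor = swFloor)
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the whitespace-separated matrix layout used by NCBI tools:
#' \code{#} comment lines, a header row of residue letters, then one row per
#' residue.
#'
#' @param path matrix file.
#' @return a numeric matrix with residue dimnames.
#' @export
readSubstitutionMatrix <- function(path) {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    rows <- strsplit(trimws(lines[-1]), "\\s+")
    mat <- t(vapply(rows, function(r) as.numeric(r[-1]),
                    numeric(length(header))))
    rownames(mat) <- vapply(rows, `[`, character(1), 1L)
    colnames(mat) <- header
    mat[header, header, drop = FALSE]
}

# residues missing from the matrix are scored through its X column
.canonicalizeSeq <- function(s, mat) {
    known <- rownames(mat)
    chars <- strsplit(s, "")[[1]]
    bad <- !chars %in% known
    if (any(bad)) {
        if (!"X" %in% known)
            stop("residue(s) absent from substitution matrix and no X column: ",
                 paste(unique(chars[bad]), collapse = ", "))
        chars[bad] <- "X"
        s <- paste(chars, collapse = "")
    }
    s
}

#' Optimal Smith-Waterman local alignment of two protein sequences
#'
#' Computes the optimal local alignment under the given scoring (affine
#' gaps; see [alignmentScoring()]), with residues unknown to the matrix
#' scored via its X column. The dynamic programming is delegated to
#' \code{\link[Biostrings]{pairwiseAlignment}}.
#'
#' @param seqA,seqB protein sequences (character or \code{AAString}).
#' @param scoring an [alignmentScoring()] list.
#' @return an [SWAlignment-class].
#' @examples
#' aln <- smithWaterman("MKTAYIAKQR", "MKTAYIAKQR")
#' aln@pctIdentity  # 100
#' @export
smithWaterman <- function(seqA, seqB, scoring = alignmentScoring()) {
    seqA <- as.character(seqA); seqB <- as.character(seqB)
    if (!nzchar(seqA) || !nzchar(seqB))
        stop("empty sequence")
    seqA <- .canonicalizeSeq(seqA, scoring$matrix)
    seqB <- .canonicalizeSeq(seqB, scoring$matrix)
    aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqA), Biostrings::AAString(seqB),
        type = "local", substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend)
    pa <- Biostrings::alignedPattern(aln)
    sa <- Biostrings::alignedSubject(aln)
    alen <- Biostrings::nchar(pa)
    new("SWAlignment",
        score = Biostrings::score(aln),
        alignedA = as.character(pa)[[1]],
        alignedB = as.character(sa)[[1]],
        pctIdentity = if (alen > 0) 100 * Biostrings::nmatch(aln) / alen
                      else 0,
        startA = as.integer(IRanges::start(Biostrings::pattern(aln))),
        endA = as.integer(IRanges::end(Biostrings::pattern(aln))),
        startB = as.integer(IRanges::start(Biostrings::subject(aln))),
        endB = as.integer(IRanges::end(Biostrings::subject(aln))))
}

# all-vs-one local scores, vectorized over the set
.swScores <- function(set, one, scoring) {
    Biostrings::pairwiseAlignment(
        set, one, type = "local", substitutionMatrix = scoring$matrix,
        gapOpening = scoring$gapOpen, gapExtension = scoring$gapExtend,
        scoreOnly = TRUE)
}

# index of the best-scoring column; ties resolved by lexicographic gene id
.argmaxTie <- function(scores, ids) {
    m <- max(scores)
    cand <- which(scores == m)
    cand[order(ids[cand])][1L]
}

#' Bidirectional best hits across a set of genomes
#'
#' For every unordered genome pair and every gene, finds the gene's
#' best-scoring partner in the other genome; a record is flagged
#' \code{best_best} when the two genes are each other's best hit (the
#' standard orthology proxy). Only records at or above the scoring's score
#' floor (default 100) are kept. Genomes with empty proteomes contribute
#' nothing (warning). Ties for best are broken by lexicographic gene id, so
#' results are deterministic.
#'
#' @param genomes list of two or more [GenomeAnnotation-class] objects.
#' @param scoring an [alignmentScoring()] list.
#' @return a similarity \code{data.frame} (see [writeSimilarityTable()]).
#' @export
bestBestHits <- function(genomes, scoring = alignmentScoring()) {
    if (length(genomes) < 2L)
        stop("need at least two genomes")
    prots <- lapply(genomes, function(g) {
        p <- g@proteome
        p[Biostrings::width(p) > 0]
    })
    empty <- lengths(prots) == 0L
    if (any(empty)) {
        warning("genome(s) with empty proteome skipped: ",
                paste(vapply(genomes[empty], orgCode, character(1)),
                      collapse = ", "), call. = FALSE)
    }
    live <- which(!empty)
    out <- list()
    for (ii in seq_along(live)) {
        for (jj in seq_len(ii - 1L)) {
            A <- prots[[live[jj]]]; B <- prots[[live[ii]]]
            sc <- vapply(seq_along(A),
                         function(k) .swScores(B, A[[k]], scoring),
                         numeric(length(B)))
            sc <- matrix(sc, nrow = length(B))  # rows = B, cols = A
            bestInB <- vapply(seq_along(A), function(k)
                .argmaxTie(sc[, k], names(B)), integer(1))
            bestInA <- vapply(seq_along(B), function(k)
                .argmaxTie(sc[k, ], names(A)), integer(1))
            pairs <- unique(rbind(
                cbind(a = seq_along(A), b = bestInB),
                cbind(a = bestInA, b = seq_along(B))))
            keep <- sc[cbind(pairs[, "b"], pairs[, "a"])] >= scoring$swFloor
            pairs <- pairs[keep, , drop = FALSE]
            if (!nrow(pairs)) next
            rec <- lapply(seq_len(nrow(pairs)), function(k) {
                ai <- pairs[k, "a"]; bi <- pairs[k, "b"]
                aln <- smithWaterman(A[[ai]], B[[bi]], scoring)
                data.frame(
                    gene_a = names(A)[ai], gene_b = names(B)[bi],
                    sw_score = as.integer(round(aln@score)),
                    pct_identity = aln@pctIdentity,
                    best_best = bestInB[ai] == bi && bestInA[bi] == ai,
                    stringsAsFactors = FALSE)
            })
            out[[length(out) + 1L]] <- do.call(rbind, rec)
        }
    }
    if (!length(out)) return(.emptySimilarity())
    .validateSimilarity(do.call(rbind, out))
}

#' Select the homolog set for a query gene
#'
#' Filters the similarity table to the query's bidirectional best hits at or
#' above the identity cutoff (at most one partner per genome), ranks them by
#' score (descending, ties by gene id), truncates to \code{nHomologs}, and
#' prepends the query itself — its own neighborhood is always analyzed.
#' A strict cutoff may leave far fewer homologs than requested; that is
#' expected and the analysis proceeds with what passes.
#'
#' @param query a [HomologQuery-class].
#' @param records similarity \code{data.frame} (see
#'   [writeSimilarityTable()]).
#' @return character vector of gene ids, query first.
#' @export
selectHomologs <- function(query, records) {
    q <- query@queryGeneId
    fwd <- records[records$gene_a == q, , drop = FALSE]
    rev <- records[records$gene_b == q, , drop = FALSE]
    cand <- data.frame(
        gene_id = c(fwd$gene_b, rev$gene_a),
        sw_score = c(fwd$sw_score, rev$sw_score),
        pct_identity = c(fwd$pct_identity, rev$pct_identity),
        best_best = c(fwd$best_best, rev$best_best),
        stringsAsFactors = FALSE)
    cand <- cand[cand$best_best & cand$pct_identity >= query@aaIdc, ,
                 drop = FALSE]
    if (nrow(cand)) {
        cand$org <- sub(":.*$", "", cand$gene_id)
        # at most one partner per genome: keep the best-scoring one
        cand <- cand[order(-cand$sw_score, cand$gene_id), , drop = FALSE]
        cand <- cand[!duplicated(cand$org), , drop = FALSE]
        cand <- utils::head(cand, query@nHomologs)
    }
    c(q, cand$gene_id)
}
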