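# Independent reference implementations used as oracles. These stay naive on
# purpose: exhaustive dynamic programming and plain loops, no shared code
# with the package internals.

# Exhaustive Gotoh local-alignment DP. A gap of length L costs
# open + L * ext, matching alignmentScoring()'s convention. Returns the
# optimal local score (0 if no positive-scoring pair alignment exists).
swOracleScore <- function(a, b, mat, open, ext) {
    A <- strsplit(a, "")[[1]]
    B <- strsplit(b, "")[[1]]
    n <- length(A); m <- length(B)
    M <- matrix(0, n + 1, m + 1)
    Ix <- matrix(-Inf, n + 1, m + 1)
    Iy <- matrix(-Inf, n + 1, m + 1)
    best <- 0
    for (i in seq_len(n)) {
        for (j in seq_len(m)) {
            Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                                    Ix[i, j + 1] - ext)
            Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                                    Iy[i + 1, j] - ext)
            s <- mat[A[i], B[j]]
            M[i + 1, j + 1] <- s + max(0, M[i, j], Ix[i, j], Iy[i, j])
            best <- max(best, M[i + 1, j + 1])
        }
    }
    best
}

# Score of a reported gapped alignment: substitution scores over aligned
# columns minus affine penalties for each gap run (open + L * ext).
scoreAlignedStrings <- function(alignedA, alignedB, mat, open, ext) {
    A <- strsplit(alignedA, "")[[1]]
    B <- strsplit(alignedB, "")[[1]]
    stopifnot(length(A) == length(B))
    score <- 0
    inGapA <- FALSE; inGapB <- FALSE
    for (k in seq_along(A)) {
        if (A[k] == "-") {
            score <- score - ext - if (inGapA) 0 else open
            inGapA <- TRUE; inGapB <- FALSE
        } else if (B[k] == "-") {
            score <- score - ext - if (inGapB) 0 else open
            inGapB <- TRUE; inGapA <- FALSE
        } else {
            score <- score + mat[A[k], B[k]]
            inGapA <- FALSE; inGapB <- FALSE
        }
    }
    score
}

randomProteinStr <- function(len) {
    paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
                 len, replace = TRUE), collapse = "")
}

# Brute-force recounts of the three summary tables, straight from the
# definitions: per-neighborhood presence for enzymes and compounds,
# frequency-weighted sums over pathway mappings.
recountEnzymes <- function(neighborhoods) {
    counts <- list()
    for (nb in neighborhoods) {
        seen <- character()
        for (i in seq_along(genes(nb))) {
            for (ec in unlist(genes(nb)$ec_numbers[i])) {
                if (!ec %in% seen) {
                    seen <- c(seen, ec)
                    counts[[ec]] <- (counts[[ec]] %||% 0L) + 1L
                }
            }
        }
    }
    counts
}

recountMetabolites <- function(neighborhoods, ref, exclude = character()) {
    ecCpds <- function(ec) {
        cpds <- character()
        for (rn in ref@ecToReactions[[ec]] %||% character()) {
            cpds <- c(cpds, ref@reactions[[rn]]$substrates,
                      ref@reactions[[rn]]$products)
        }
        unique(cpds)
    }
    counts <- list()
    for (nb in neighborhoods) {
        cpds <- character()
        for (i in seq_along(genes(nb))) {
            for (ec in unlist(genes(nb)$ec_numbers[i]))
                cpds <- c(cpds, ecCpds(ec))
        }
        for (cp in setdiff(unique(cpds), exclude))
            counts[[cp]] <- (counts[[cp]] %||% 0L) + 1L
    }
    counts
}

recountPathways <- function(ecCounts, cpdCounts, ref) {
    hits <- list()
    for (ec in names(ecCounts)) {
        for (p in ref@ecToPathways[[ec]] %||% character())
            hits[[p]] <- (hits[[p]] %||% 0L) + ecCounts[[ec]]
    }
    for (cp in names(cpdCounts)) {
        for (p in ref@compoundToPathways[[cp]] %||% character())
            hits[[p]] <- (hits[[p]] %||% 0L) + cpdCounts[[cp]]
    }
    hits
}

# named-list vs summary-table comparison
expectSummaryEqual <- function(df, counts, idCol, nCol) {
    expect_setequal(df[[idCol]], names(counts))
    got <- stats::setNames(df[[nCol]], df[[idCol]])
    for (id in names(counts))
        expect_identical(as.integer(got[[id]]), as.integer(counts[[id]]))
}

# dense grid search for the Hill fit, profiling deltaAT analytically:
# for fixed (kd, h) the model is linear in deltaAT
hillGridOracle <- function(points, kdGrid, hGrid) {
    best <- list(rss = Inf)
    for (kd in kdGrid) {
        for (h in hGrid) {
            f <- points$E^h / (kd^h + points$E^h)
            dAT <- sum(f * points$delta_A) / sum(f^2)
            rss <- sum((points$delta_A - dAT * f)^2)
            if (rss < best$rss)
                best <- list(kd = kd, h = h, deltaAT = dAT, rss = rss)
        }
    }
    best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
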