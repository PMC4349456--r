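#' @include AllClasses.R context.R
NULL

.htmlEscape <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
}

# entity id -> <a href> when a link template is configured, plain text else
.linkify <- function(ids, linkBase) {
    esc <- .htmlEscape(ids)
    if (is.null(linkBase) || !length(ids)) return(esc)
    href <- if (grepl("%s", linkBase, fixed = TRUE)) {
        vapply(ids, function(i) sprintf(linkBase, i), character(1))
    } else {
        paste0(linkBase, ids)
    }
    sprintf("<a href=\"%s\">%s</a>", .htmlEscape(href), esc)
}

.htmlTable <- function(df, linkCol = NULL, linkBase = NULL) {
    if (!nrow(df)) return("<p class=\"empty\">empty table</p>")
    cells <- lapply(names(df), function(cn) {
        v <- as.character(df[[cn]])
        if (!is.null(linkCol) && cn == linkCol) .linkify(v, linkBase)
        else .htmlEscape(v)
    })
    head <- paste0("<tr>", paste0("<th>", .htmlEscape(names(df)), "</th>",
                                  collapse = ""), "</tr>")
    body <- vapply(seq_len(nrow(df)), function(i) {
        paste0("<tr>", paste0("<td>",
                              vapply(cells, `[`, character(1), i),
                              "</td>", collapse = ""), "</tr>")
    }, character(1))
    paste0("<table>\n", head, "\n", paste(body, collapse = "\n"),
           "\n</table>")
}

#' Render a neighborhood analysis as a self-contained HTML report
#'
#' Writes the five report sections in fixed order — Homolog ID, Neighborhood
#' Representations (one row per homolog, anchor highlighted, genes labeled
#' by product/EC), then the Over-represented Enzyme, Metabolite and Pathway
#' Summaries. Entity ids are hyperlinked through \code{linkBase} (a template
#' containing \code{\%s}, or a prefix) when given, plain text otherwise. The
#' output carries no timestamps and is byte-identical across repeated runs
#' on the same result. An empty pathway table renders as an explicit "no
#' pathway mapping available" notice rather than being dropped.
#'
#' @param result a [NeighborhoodAnalysis-class].
#' @param out output HTML path.
#' @param linkBase optional URL template for entity hyperlinks.
#' @return invisibly, \code{out}.
#' @seealso [renderJson()]
#' @export
renderHtml <- function(result, out, linkBase = NULL) {
    q <- result@query
    homTab <- data.frame(
        rank = seq_along(result@homologs),
        gene_id = result@homologs,
        organism = sub(":.*$", "", result@homologs),
        neighborhood_genes = vapply(result@neighborhoods,
                                    function(nb) length(nb@genes),
                                    integer(1)),
        role = c("query", rep("homolog", length(result@homologs) - 1L)),
        stringsAsFactors = FALSE)
    nbRows <- vapply(result@neighborhoods, function(nb) {
        lab <- vapply(seq_along(nb@genes), function(i) {
            g <- nb@genes[i]
            ec <- unlist(g$ec_numbers)
            txt <- if (length(ec)) paste(ec, collapse = " ")
                   else if (nzchar(g$product)) g$product else g$gene_id
            cls <- if (g$gene_id == nb@anchorGeneId) " class=\"anchor\""
                   else ""
            paste0("<td", cls, ">", .htmlEscape(txt), "</td>")
        }, character(1))
        paste0("<tr><th>", .htmlEscape(nb@anchorGeneId), "</th>",
               paste(lab, collapse = ""), "</tr>")
    }, character(1))
    pathHtml <- if (nrow(result@pathwaySummary)) {
        .htmlTable(result@pathwaySummary, "pathway", linkBase)
    } else {
        paste0("<p class=\"empty\">no pathway mapping available for the ",
               "summarized enzymes and metabolites</p>")
    }
    html <- c(
        "<!DOCTYPE html>",
        "<html><head><meta charset=\"utf-8\">",
        paste0("<title>Neighborhood analysis: ",
               .htmlEscape(q@queryGeneId), "</title>"),
        "<style>",
        "body{font-family:sans-serif;margin:2em}",
        "table{border-collapse:collapse;margin:1em 0}",
        "td,th{border:1px solid #999;padding:2px 6px;font-size:90%}",
        "td.anchor{background:#ffe08a;font-weight:bold}",
        ".empty{color:#666;font-style:italic}",
        "</style></head><body>",
        paste0("<h1>Gene neighborhood analysis of ",
               .htmlEscape(q@queryGeneId), "</h1>"),
        paste0("<p>parameters: nHomologs=", q@nHomologs,
               ", aaIdc=", q@aaIdc, "%, nNeighbors=", q@nNeighbors,
               ", scoreMode=", result@scoreMode, "</p>"),
        "<h2>Homolog ID</h2>",
        .htmlTable(homTab, "gene_id", linkBase),
        "<h2>Neighborhood Representations</h2>",
        "<table>", nbRows, "</table>",
        "<h2>Over-represented Enzyme Summary</h2>",
        .htmlTable(result@enzymeSummary, "ec", linkBase),
        "<h2>Over-represented Metabolite Summary</h2>",
        .htmlTable(result@metaboliteSummary, "compound", linkBase),
        "<h2>Over-represented Pathway Summary</h2>",
        pathHtml,
        "</body></html>")
    con <- file(out, open = "wb")  # fixed EOL across platforms
    on.exit(close(con))
    writeLines(html, con, sep = "\n")
    invisible(out)
}

.neighborhoodAsList <- function(nb) {
    g <- nb@genes
    list(
        anchor = nb@anchorGeneId,
        genes = data.frame(
            gene_id = g$gene_id,
            replicon_id = as.character(GenomicRanges::seqnames(g)),
            index = g$index,
            start = GenomicRanges::start(g),
            end = GenomicRanges::end(g),
            strand = as.character(GenomicRanges::strand(g)),
            product = g$product,
            ec_numbers = vapply(g$ec_numbers, paste, character(1),
                                collapse = ";"),
            stringsAsFactors = FALSE))
}

#' Render a neighborhood analysis as machine-readable JSON
#'
#' Lossless, schema-versioned serialization of the homolog list, every
#' neighborhood's gene table, and the three summary tables, with the same
#' row order as the HTML report (both are rendered from the one in-memory
#' result). [readAnalysisJson()] loads it back as plain lists/data frames.
#'
#' @param result a [NeighborhoodAnalysis-class].
#' @param out output JSON path.
#' @return invisibly, \code{out}.
#' @export
renderJson <- function(result, out) {
    q <- result@query
    doc <- list(
        schema_version = "1.0",
        query = list(queryGeneId = q@queryGeneId,
                     nHomologs = q@nHomologs, aaIdc = q@aaIdc,
                     nNeighbors = q@nNeighbors,
                     scoreMode = result@scoreMode),
        homologs = result@homologs,
        neighborhoods = lapply(result@neighborhoods, .neighborhoodAsList),
        enzyme_summary = result@enzymeSummary,
        metabolite_summary = result@metaboliteSummary,
        pathway_summary = result@pathwaySummary)
    jsonlite::write_json(doc, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(out)
}

#' @rdname renderJson
#' @param path a JSON file written by \code{renderJson}.
#' @return \code{readAnalysisJson}: a list mirroring the document, with the
#'   summaries as \code{data.frame}s.
#' @export
readAnalysisJson <- function(path) {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    fix <- function(df, int) {
        if (!is.data.frame(df) || !nrow(df)) {
            return(data.frame())
        }
        df[[int]] <- as.integer(df[[int]])
        df
    }
    doc$enzyme_summary <- fix(doc$enzyme_summary, "frequency")
    doc$metabolite_summary <- fix(doc$metabolite_summary, "frequency")
    doc$pathway_summary <- fix(doc$pathway_summary, "hits")
    doc
}
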