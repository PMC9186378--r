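#' Read an expression matrix from TSV
#'
#' Expects genes as rows, samples as columns, a header row, and the gene id
#' in the first column.
#'
#' @param path file path.
#' @param isLog whether values are already log2-scale.
#' @param pseudocount pseudocount recorded with log-scale data.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpressionTsv <- function(path, isLog = FALSE, pseudocount = 1) {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    storage.mode(m) <- "double"
    ExpressionMatrix(m, isLog = isLog, pseudocount = pseudocount)
}

#' Write an expression matrix to TSV
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path file path; first column \code{gene}, then one column per sample.
#' @export
writeExpressionTsv <- function(x, path) {
    v <- exprValues(x)
    df <- data.frame(gene = rownames(v), v, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated, name, description, then
#' member gene ids.
#'
#' @param path file path.
#' @return Named list of character vectors of gene ids.
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    sets <- lapply(lines, function(l) {
        parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
        unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
    })
    names(sets) <- vapply(lines, function(l)
        strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
    sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param description optional description field (recycled).
#' @export
writeGmt <- function(sets, path, description = "na") {
    stopifnot(!is.null(names(sets)))
    lines <- mapply(function(nm, genes, desc)
        paste(c(nm, desc, genes), collapse = "\t"),
        names(sets), sets, rep_len(description, length(sets)))
    writeLines(lines, path)
    invisible(path)
}

#' Read an undirected graph from a two-column edge-list TSV
#'
#' @param path file path with columns \code{from}, \code{to} (header
#'   optional: detected when the first row is non-duplicated column names
#'   "from"/"to").
#' @return An edge data.frame with columns \code{from}, \code{to}; attribute
#'   \code{nodes} carries isolated nodes if a \code{#nodes:} comment line
#'   listed them.
#' @export
readEdgeListTsv <- function(path) {
    first <- readLines(path, n = 1)
    header <- identical(tolower(strsplit(first, "\t")[[1]][1:2]),
                        c("from", "to"))
    df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
    names(df)[1:2] <- c("from", "to")
    df[, 1:2]
}

#' Write an undirected graph as an edge-list TSV
#'
#' @param edges data.frame with columns \code{from}, \code{to}.
#' @param path file path.
#' @export
writeEdgeListTsv <- function(edges, path) {
    utils::write.table(edges[, c("from", "to")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a genomic gene order from a BED-like TSV
#'
#' Columns: chrom, start, end, gene. Genes are sorted by (chrom, start).
#'
#' @param path file path.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end},
#'   \code{gene}, sorted by genomic location.
#' @export
readGeneOrderBed <- function(path) {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                            col.names = c("chrom", "start", "end", "gene"))
    df[order(df$chrom, df$start), , drop = FALSE]
}
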