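#' Single-cell QC thresholds
#'
#' Defaults follow the standard droplet scRNA-seq rules: drop genes detected
#' in fewer than 3 cells, cells detecting fewer than 200 or more than 4,500
#' genes, and cells whose mitochondrial transcripts exceed 10%.
#'
#' @param minCellsPerGene genes detected (count > 0) in fewer cells are
#'   removed.
#' @param minGenesPerCell,maxGenesPerCell allowed detected-gene range per
#'   cell; cells strictly outside are removed.
#' @param maxMitoFraction cells with a strictly larger mitochondrial
#'   transcript fraction are removed.
#' @return A \code{QcThresholds} list.
#' @export
qcThresholds <- function(minCellsPerGene = 3, minGenesPerCell = 200,
                         maxGenesPerCell = 4500, maxMitoFraction = 0.10) {
    stopIf(minGenesPerCell >= maxGenesPerCell,
           "invalid QcThresholds: minGenesPerCell must be < maxGenesPerCell")
    structure(list(minCellsPerGene = minCellsPerGene,
                   minGenesPerCell = minGenesPerCell,
                   maxGenesPerCell = maxGenesPerCell,
                   maxMitoFraction = maxMitoFraction),
              class = "QcThresholds")
}

#' Quality-control filtering of a raw count matrix
#'
#' Genes are filtered first (detected in fewer than
#' \code{thr$minCellsPerGene} cells), then cells whose detected-gene count
#' falls strictly outside \code{[minGenesPerCell, maxGenesPerCell]} or whose
#' mitochondrial transcript fraction strictly exceeds
#' \code{thr$maxMitoFraction}. Survivor order is preserved. All comparisons
#' are strict, matching the conventional statement of the rules.
#'
#' @param raw a count-scale \linkS4class{ExpressionMatrix}.
#' @param thr a \code{\link{qcThresholds}} object.
#' @param mitoPrefix gene-name prefix identifying mitochondrial genes.
#' @return List with \code{filtered} (\linkS4class{ExpressionMatrix}) and
#'   \code{report} (genes/cells removed and kept).
#' @export
qcFilter <- function(raw, thr = qcThresholds(), mitoPrefix = "MT-") {
    stopifnot(is(raw, "ExpressionMatrix"))
    stopIf(isLogScale(raw), "qcFilter requires count-scale input, got log-scale")
    v <- exprValues(raw)
    detectedCells <- rowSums(v > 0)
    keepGene <- detectedCells >= thr$minCellsPerGene
    v1 <- v[keepGene, , drop = FALSE]
    stopIf(nrow(v1) == 0, "all filtered: no genes survive QC")

    genesPerCell <- colSums(v1 > 0)
    mitoRows <- startsWith(rownames(v1), mitoPrefix)
    total <- colSums(v1)
    mitoFrac <- ifelse(total > 0, colSums(v1[mitoRows, , drop = FALSE]) / total, 0)
    keepCell <- genesPerCell >= thr$minGenesPerCell &
        genesPerCell <= thr$maxGenesPerCell &
        mitoFrac <= thr$maxMitoFraction
    v2 <- v1[, keepCell, drop = FALSE]
    stopIf(nrow(v2) == 0 || ncol(v2) == 0,
           "all filtered: no %s survive QC", if (nrow(v2) == 0) "genes" else "cells")
    list(filtered = ExpressionMatrix(v2),
         report = list(genesRemoved = sum(!keepGene),
                       cellsRemoved = sum(!keepCell),
                       genesKept = nrow(v2), cellsKept = ncol(v2),
                       mitoFraction = mitoFrac))
}

#' Per-gene two-group Wilcoxon rank-sum differential expression
#'
#' For each gene, a two-sided Wilcoxon rank-sum test (normal approximation
#' with continuity and tie correction) between groups A and B on log2-scale
#' expression, with \code{log2FC = mean(A) - mean(B)} of log2 values and
#' Benjamini-Hochberg FDR over all tested genes.
#'
#' @param expr an \linkS4class{ExpressionMatrix}; log2(x+1) is applied if the
#'   matrix is on linear scale.
#' @param groupA,groupB disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @return A \code{DeTable} data.frame with columns \code{gene},
#'   \code{log2fc}, \code{p}, \code{fdr}.
#' @export
wilcoxonDe <- function(expr, groupA, groupB) {
    stopifnot(is(expr, "ExpressionMatrix"))
    stopIf(length(intersect(groupA, groupB)) > 0,
           "groups overlap: %s", paste(intersect(groupA, groupB), collapse = ", "))
    unknown <- setdiff(c(groupA, groupB), sampleIds(expr))
    stopIf(length(unknown) > 0, "unknown sample ids: %s",
           paste(utils::head(unknown, 5), collapse = ", "))
    stopIf(length(groupA) < 2 || length(groupB) < 2,
           "each group needs >= 2 samples")
    lv <- exprValues(asLogScale(expr))
    a <- lv[, groupA, drop = FALSE]
    b <- lv[, groupB, drop = FALSE]
    p <- vapply(seq_len(nrow(lv)), function(i) {
        x <- a[i, ]; y <- b[i, ]
        if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) return(1)
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE)$p.value)
    }, numeric(1))
    p[is.na(p)] <- 1
    data.frame(gene = rownames(lv),
               log2fc = rowMeans(a) - rowMeans(b),
               p = p, fdr = stats::p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Split a DE table into early/late differentiation signatures
#'
#' Genes with \code{log2fc > lfcCut} and \code{fdr < fdrCut} form the early
#' signature; \code{log2fc < -lfcCut} (same FDR rule) the late signature.
#' Both comparisons are strict; the sets are disjoint by construction.
#'
#' @param de a DE table from \code{\link{wilcoxonDe}}.
#' @param lfcCut absolute log2-fold-change threshold (default 1.3).
#' @param fdrCut FDR threshold (default 0.05).
#' @return List with character vectors \code{early} and \code{late}.
#' @export
splitSignatures <- function(de, lfcCut = 1.3, fdrCut = 0.05) {
    list(early = de$gene[de$log2fc > lfcCut & de$fdr < fdrCut],
         late = de$gene[de$log2fc < -lfcCut & de$fdr < fdrCut])
}

#' Threshold a DE table into a cohort DEG set
#'
#' Strict thresholds in one direction, supporting cohort-specific cutoffs
#' (e.g. |log2FC| > 1 for RNA-seq, > 0.2 for arrays); intersect the returned
#' sets across cohorts with \code{intersect()}.
#'
#' @param de a DE table.
#' @param lfcCut log2-fold-change threshold (strict).
#' @param fdrCut FDR threshold (strict).
#' @param direction \code{"up"} (log2fc > lfcCut) or \code{"down"}
#'   (log2fc < -lfcCut).
#' @return Character vector of gene ids.
#' @export
cohortDegs <- function(de, lfcCut, fdrCut = 0.05,
                       direction = c("up", "down")) {
    direction <- match.arg(direction)
    if (nrow(de) == 0) return(character())
    keep <- if (direction == "up") de$log2fc > lfcCut else de$log2fc < -lfcCut
    de$gene[keep & de$fdr < fdrCut]
}
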