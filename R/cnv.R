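#' Windowed relative copy-number profile from expression
#'
#' For each cell, expression is log2(x+1)-transformed, centred by the
#' per-gene mean over the reference cells, clipped to \code{[-clip, clip]},
#' and averaged over a sliding window of \code{2 * halfWindow + 1} genes
#' ordered by genomic location (a 101-gene window by default). Windows never
#' span chromosomes; at chromosome ends the window truncates and divides by
#' the actual member count.
#'
#' @param expr an \linkS4class{ExpressionMatrix} (counts or log scale; the
#'   log2(x+1) transform is applied when needed).
#' @param referenceCells non-empty character vector of reference cell ids
#'   (e.g. normal cells).
#' @param order data.frame with columns \code{chrom}, \code{gene} (and
#'   optionally \code{start}), giving the genomic gene order; every listed
#'   gene must be present in \code{expr}.
#' @param halfWindow genes on each side of the centre (default 50).
#' @param clip symmetric clipping bound on centred values before windowing
#'   (default 3; \code{Inf} disables).
#' @return cells x ordered-genes numeric matrix of relative copy-number
#'   scores (log2-ratio units).
#' @export
inferCnvProfile <- function(expr, referenceCells, order, halfWindow = 50,
                            clip = 3) {
    stopifnot(is(expr, "ExpressionMatrix"),
              all(c("chrom", "gene") %in% names(order)))
    stopIf(length(referenceCells) == 0, "empty reference cell set")
    missRef <- setdiff(referenceCells, sampleIds(expr))
    stopIf(length(missRef) > 0, "reference cells missing from expr: %s",
           paste(utils::head(missRef, 5), collapse = ", "))
    missing <- setdiff(order$gene, geneIds(expr))
    stopIf(length(missing) > 0, "genes in order missing from expr: %s",
           paste(utils::head(missing, 10), collapse = ", "))
    lv <- exprValues(asLogScale(expr))[order$gene, , drop = FALSE]
    E <- lv - rowMeans(lv[, referenceCells, drop = FALSE])
    E <- pmin(pmax(E, -clip), clip)

    prof <- matrix(NA_real_, ncol(E), nrow(E),
                   dimnames = list(colnames(E), order$gene))
    for (chr in unique(order$chrom)) {
        rows <- which(order$chrom == chr)
        nG <- length(rows)
        Echr <- E[rows, , drop = FALSE]
        cs <- apply(Echr, 2, cumsum)
        if (nG == 1) cs <- matrix(cs, nrow = 1)
        lo <- pmax(seq_len(nG) - halfWindow, 1L)
        hi <- pmin(seq_len(nG) + halfWindow, nG)
        width <- hi - lo + 1L
        for (j in seq_len(ncol(Echr))) {
            c0 <- c(0, cs[, j])
            prof[j, rows] <- (c0[hi + 1L] - c0[lo]) / width
        }
    }
    prof
}

#' Call copy-number gain/loss from focal values
#'
#' Values strictly greater than \code{+threshold} are gains, strictly less
#' than \code{-threshold} losses, anything else neutral (symmetric-threshold
#' rule).
#'
#' @param x numeric vector/matrix of focal copy-number values.
#' @param threshold symmetric call threshold (default 0.2).
#' @return Character object of the same shape with entries \code{"gain"},
#'   \code{"neutral"}, \code{"loss"}.
#' @export
callGainLoss <- function(x, threshold = 0.2) {
    stopIf(any(!is.finite(x)), "values must be finite")
    out <- ifelse(x > threshold, "gain", ifelse(x < -threshold, "loss",
                                                "neutral"))
    if (is.matrix(x)) dimnames(out) <- dimnames(x)
    out
}
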