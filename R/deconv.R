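#' Immune-cell fraction deconvolution by constrained least squares
#'
#' Estimates the composition of each bulk sample over a reference basis of
#' cell-type expression profiles (an LM22-style signature matrix). Per
#' sample, fractions minimize \eqn{\|B f - y\|_2} subject to \eqn{f \ge 0}
#' (non-negative least squares), then are renormalized to sum to 1. Fitting
#' is restricted to the genes shared between bulk and basis, and both sides
#' are standardized per gene by the basis row standard deviation, which
#' stabilizes the fit while keeping it exactly linear (so noiseless mixtures
#' are recovered exactly and the result is invariant to positive rescaling
#' of a sample).
#'
#' @param bulk a linear-scale \linkS4class{ExpressionMatrix}.
#' @param basis genes x cell-types non-negative numeric matrix with dimnames.
#' @return A \linkS4class{CellFractions} (samples x cell types).
#' @export
deconvolve <- function(bulk, basis) {
    stopifnot(is(bulk, "ExpressionMatrix"), is.matrix(basis))
    stopIf(isLogScale(bulk), "deconvolve requires linear-scale bulk expression")
    stopIf(any(basis < 0), "basis must be non-negative")
    shared <- intersect(geneIds(bulk), rownames(basis))
    stopIf(length(shared) < ncol(basis),
           "only %d shared genes for %d cell types", length(shared), ncol(basis))
    B <- basis[shared, , drop = FALSE]
    Y <- exprValues(bulk)[shared, , drop = FALSE]
    zero <- colSums(Y) == 0
    stopIf(any(zero), "all-zero sample(s): %s",
           paste(colnames(Y)[zero], collapse = ", "))
    w <- apply(B, 1, stats::sd)
    w[w == 0] <- 1
    Bw <- B / w
    Yw <- Y / w
    F <- t(vapply(seq_len(ncol(Yw)), function(j) {
        f <- pracma::lsqnonneg(Bw, Yw[, j])$x
        if (sum(f) == 0) f else f / sum(f)
    }, numeric(ncol(B))))
    dimnames(F) <- list(colnames(Y), colnames(B))
    CellFractions(F)
}

#' Immune and stromal sample scores
#'
#' Rank-based single-sample enrichment (\code{\link{ssgsea}}) of a
#' user-supplied immune gene set and stromal gene set, one score of each per
#' sample. Scores are invariant to monotone transforms of a sample's
#' expression.
#'
#' @param expr an \linkS4class{ExpressionMatrix}.
#' @param immuneSet,stromalSet character vectors of gene ids; each must
#'   overlap the expression genes.
#' @param ... passed to \code{\link{ssgsea}}.
#' @return data.frame with columns \code{sample}, \code{immuneScore},
#'   \code{stromalScore}.
#' @export
immuneStromalScore <- function(expr, immuneSet, stromalSet, ...) {
    s <- ssgsea(expr, list(immune = immuneSet, stromal = stromalSet), ...)
    data.frame(sample = rownames(s), immuneScore = s[, "immune"],
               stromalScore = s[, "stromal"], row.names = NULL,
               stringsAsFactors = FALSE)
}
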