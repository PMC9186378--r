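#' @import methods
NULL

#' ExpressionMatrix: genes x samples expression values
#'
#' The universal currency of the pipeline: a numeric matrix with genes as
#' rows and cells/samples as columns, plus a flag recording whether the
#' values are on log2 scale (and, if so, the pseudocount used).
#'
#' @slot values numeric matrix, genes x samples, with dimnames.
#' @slot isLog logical; \code{TRUE} when values are log2(x + pseudocount).
#' @slot pseudocount numeric pseudocount used for the log transform.
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix",
    representation(values = "matrix", isLog = "logical",
                   pseudocount = "numeric"),
    prototype(isLog = FALSE, pseudocount = 1))

setValidity("ExpressionMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must have gene (row) and sample (column) names")
    else {
        if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate gene ids")
        if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample ids")
    }
    if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
    if (!object@isLog && any(v < 0))
        msg <- c(msg, "values must be >= 0 on non-log scale")
    if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values genes x samples numeric matrix with dimnames.
#' @param isLog logical; are values on log2 scale already?
#' @param pseudocount pseudocount used when log-transforming.
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, isLog = FALSE, pseudocount = 1) {
    new("ExpressionMatrix", values = values, isLog = isLog,
        pseudocount = pseudocount)
}

#' CellFractions: samples x cell-type composition
#'
#' Rows are samples, columns immune cell types; each row is a point on the
#' probability simplex (non-negative, sums to 1).
#'
#' @slot values numeric matrix, samples x cell types, with dimnames.
#' @exportClass CellFractions
setClass("CellFractions", representation(values = "matrix"))

setValidity("CellFractions", function(object) {
    v <- object@values
    msg <- character()
    if (is.null(rownames(v)) || is.null(colnames(v)))
        msg <- c(msg, "values must have sample (row) and cell-type (column) names")
    if (any(v < -1e-12)) msg <- c(msg, "fractions must be non-negative")
    if (any(abs(rowSums(v) - 1) > 1e-6))
        msg <- c(msg, "each row must sum to 1 within 1e-6")
    if (length(msg)) msg else TRUE
})

#' Construct a CellFractions object
#' @param values samples x cell-types matrix of fractions (rows on simplex).
#' @return A \linkS4class{CellFractions}.
#' @export
CellFractions <- function(values) new("CellFractions", values = values)

#' ConsensusResult: output of resampled consensus clustering
#'
#' @slot k integer cluster count.
#' @slot consensusMatrix samples x samples co-clustering proportions.
#' @slot labels named integer cluster assignment in 1..k.
#' @slot pacScore proportion of ambiguous clustering (consensus entries
#'   strictly inside (0.1, 0.9)).
#' @exportClass ConsensusResult
setClass("ConsensusResult",
    representation(k = "integer", consensusMatrix = "matrix",
                   labels = "integer", pacScore = "numeric"))

setValidity("ConsensusResult", function(object) {
    m <- object@consensusMatrix
    msg <- character()
    if (any(m < -1e-12 | m > 1 + 1e-12))
        msg <- c(msg, "consensus entries must lie in [0,1]")
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
        msg <- c(msg, "consensus matrix must be symmetric")
    if (any(abs(diag(m) - 1) > 1e-8))
        msg <- c(msg, "consensus diagonal must be 1")
    if (any(object@labels < 1L | object@labels > object@k))
        msg <- c(msg, "labels must be in 1..k")
    if (length(msg)) msg else TRUE
})

#' MlpModel: a small feed-forward neural network
#'
#' Layer sizes 7-20-5-1 by default, logistic sigmoid at every layer.
#' Weights/biases are stored per layer; feature normalization constants are
#' kept with the model so prediction reuses the training-time scaling.
#'
#' @slot layerSizes integer vector of layer widths (input first).
#' @slot weights list of weight matrices (out x in per layer).
#' @slot biases list of bias vectors.
#' @slot dropoutRate numeric dropout rate applied to hidden layers in
#'   training.
#' @slot featureNames character feature schema.
#' @slot featureCenter,featureScale numeric z-scoring constants per feature.
#' @slot training list of training configuration (lr, epochs, seed) and the
#'   loss trace.
#' @exportClass MlpModel
setClass("MlpModel",
    representation(layerSizes = "integer", weights = "list", biases = "list",
                   dropoutRate = "numeric", featureNames = "character",
                   featureCenter = "numeric", featureScale = "numeric",
                   training = "list"))

setValidity("MlpModel", function(object) {
    L <- length(object@layerSizes)
    msg <- character()
    if (length(object@weights) != L - 1 || length(object@biases) != L - 1)
        msg <- c(msg, "need one weight matrix and bias per layer transition")
    else for (l in seq_len(L - 1)) {
        w <- object@weights[[l]]
        if (!all(dim(w) == c(object@layerSizes[l + 1], object@layerSizes[l])))
            msg <- c(msg, sprintf("weight %d has wrong shape", l))
        if (length(object@biases[[l]]) != object@layerSizes[l + 1])
            msg <- c(msg, sprintf("bias %d has wrong length", l))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ExpressionMatrix", function(object) {
    cat(sprintf("ExpressionMatrix: %d genes x %d samples (%s scale)\n",
        nrow(object@values), ncol(object@values),
        if (object@isLog) sprintf("log2, pseudocount %g", object@pseudocount)
        else "linear"))
})

setMethod("show", "CellFractions", function(object) {
    cat(sprintf("CellFractions: %d samples x %d cell types (rows on simplex)\n",
        nrow(object@values), ncol(object@values)))
})

setMethod("show", "ConsensusResult", function(object) {
    cat(sprintf("ConsensusResult: k = %d, %d samples, PAC = %.3f\n",
        object@k, nrow(object@consensusMatrix), object@pacScore))
})

setMethod("show", "MlpModel", function(object) {
    cat(sprintf("MlpModel: layers [%s], sigmoid activations, dropout %.2f\n",
        paste(object@layerSizes, collapse = ", "), object@dropoutRate))
})
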