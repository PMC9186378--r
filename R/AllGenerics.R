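#' Accessors for the core classes
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @describeIn accessors the underlying numeric matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)

#' @describeIn accessors gene identifiers (rows).
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))

#' @describeIn accessors sample/cell identifiers.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
setMethod("sampleIds", "CellFractions", function(x) rownames(x@values))

#' @describeIn accessors is the matrix on log2 scale?
#' @export
setGeneric("isLogScale", function(x) standardGeneric("isLogScale"))
setMethod("isLogScale", "ExpressionMatrix", function(x) x@isLog)

#' @describeIn accessors samples x cell-types fraction matrix.
#' @export
setGeneric("fractionValues", function(x) standardGeneric("fractionValues"))
setMethod("fractionValues", "CellFractions", function(x) x@values)

#' @describeIn accessors cell-type identifiers.
#' @export
setGeneric("cellTypeIds", function(x) standardGeneric("cellTypeIds"))
setMethod("cellTypeIds", "CellFractions", function(x) colnames(x@values))

#' @describeIn accessors cluster labels of a consensus run.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
setMethod("clusterLabels", "ConsensusResult", function(x) x@labels)

#' @describeIn accessors samples x samples consensus proportions.
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensusMatrix)

#' @describeIn accessors proportion of ambiguous clustering.
#' @export
setGeneric("pacScore", function(x) standardGeneric("pacScore"))
setMethod("pacScore", "ConsensusResult", function(x) x@pacScore)

#' Return a log2-scale copy of an ExpressionMatrix
#'
#' Applies log2(x + pseudocount) unless the matrix is already on log scale.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param pseudocount pseudocount for the transform (default 1).
#' @return An \linkS4class{ExpressionMatrix} on log2 scale.
#' @export
setGeneric("asLogScale", function(x, pseudocount = 1)
    standardGeneric("asLogScale"))
setMethod("asLogScale", "ExpressionMatrix", function(x, pseudocount = 1) {
    if (x@isLog) return(x)
    ExpressionMatrix(log2(x@values + pseudocount), isLog = TRUE,
                     pseudocount = pseudocount)
})

#' Return a linear-scale copy of an ExpressionMatrix
#'
#' Inverts the stored log2(x + pseudocount) transform when needed.
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @return An \linkS4class{ExpressionMatrix} on linear scale.
#' @export
setGeneric("asLinearScale", function(x) standardGeneric("asLinearScale"))
setMethod("asLinearScale", "ExpressionMatrix", function(x) {
    if (!x@isLog) return(x)
    v <- pmax(2^x@values - x@pseudocount, 0)
    ExpressionMatrix(v, isLog = FALSE, pseudocount = x@pseudocount)
})
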