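#' Single-sample gene-set enrichment (ssGSEA)
#'
#' Rank-based per-sample enrichment in the weighted running-sum form. For a
#' sample, genes receive average-tie ranks (largest expression = largest
#' rank) and are walked in decreasing rank order. In-set genes contribute
#' increments proportional to rank^\code{alpha}, out-set genes increments of
#' 1/(N - |set|); the enrichment score is the sum over positions of the
#' difference of the two cumulative fractions. With \code{normalize = TRUE}
#' all scores are rescaled by the global max - min across the whole score
#' matrix.
#'
#' @param expr an \linkS4class{ExpressionMatrix}; scores depend on
#'   within-sample ranks only, so the scale (log or linear) is irrelevant up
#'   to monotone transforms.
#' @param sets named list of gene-id vectors; each must overlap the
#'   expression genes.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize rescale by the global score range (default TRUE).
#' @return Numeric matrix, samples x sets.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
    stopifnot(is(expr, "ExpressionMatrix"), is.list(sets))
    if (is.null(names(sets)))
        names(sets) <- sprintf("set%02d", seq_along(sets))
    v <- exprValues(expr)
    genes <- rownames(v)
    for (nm in names(sets))
        stopIf(length(intersect(sets[[nm]], genes)) == 0,
               "gene set '%s' has zero overlap with expression genes", nm)
    inSet <- vapply(sets, function(s) genes %in% s, logical(nrow(v)))
    if (is.null(dim(inSet))) inSet <- matrix(inSet, nrow = 1)
    N <- nrow(v)
    scores <- matrix(NA_real_, ncol(v), length(sets),
                     dimnames = list(colnames(v), names(sets)))
    for (j in seq_len(ncol(v))) {
        r <- rank(v[, j], ties.method = "average")
        ord <- order(r, decreasing = TRUE)
        rw <- r[ord]^alpha
        for (k in seq_along(sets)) {
            m <- inSet[ord, k]
            nIn <- sum(m)
            cumIn <- cumsum(ifelse(m, rw, 0)) / sum(rw[m])
            cumOut <- if (N > nIn) cumsum(!m) / (N - nIn) else rep(0, N)
            scores[j, k] <- sum(cumIn - cumOut)
        }
    }
    if (normalize) {
        rng <- max(scores) - min(scores)
        if (rng > 0) scores <- scores / rng
    }
    scores
}

#' Median split of sample scores into immune hot and cold
#'
#' Scores strictly above the cohort median are \code{"hot"}; scores at or
#' below the median are \code{"cold"} (ties at the exact median are assigned
#' cold, a deterministic and conservative rule).
#'
#' @param scores named numeric vector of per-sample scores (>= 2 samples).
#' @return Named character vector of \code{"hot"}/\code{"cold"} labels.
#' @export
hotColdSplit <- function(scores) {
    stopIf(length(scores) < 2, "need >= 2 samples to split")
    stopIf(max(scores) == min(scores),
           "all scores identical: no hot/cold split possible")
    med <- stats::median(scores)
    stats::setNames(ifelse(scores > med, "hot", "cold"), names(scores))
}

#' Hot-vs-cold fold change of immune-related scores
#'
#' For each signature column, the difference of group means,
#' mean(score | hot) - mean(score | cold). When \code{includeSum} is TRUE a
#' \code{"immune_related_sum"} entry is appended for the per-sample sum of
#' all columns (the combined immune-related score).
#'
#' @param scores numeric matrix (samples x signatures, rownames = sample
#'   ids) or a named per-sample vector.
#' @param labels named \code{"hot"}/\code{"cold"} labels covering the same
#'   samples.
#' @param includeSum append the summed-score fold change (default TRUE for
#'   matrices).
#' @return Named numeric vector of fold changes.
#' @export
signatureFoldChange <- function(scores, labels, includeSum = is.matrix(scores)) {
    force(includeSum)
    if (!is.matrix(scores))
        scores <- matrix(scores, ncol = 1,
                         dimnames = list(names(scores), "score"))
    stopIf(is.null(rownames(scores)) || is.null(names(labels)),
           "scores and labels must carry sample ids")
    common <- intersect(rownames(scores), names(labels))
    stopIf(length(common) != nrow(scores),
           "scores and labels must share all sample ids")
    lab <- labels[rownames(scores)]
    stopIf(!any(lab == "hot") || !any(lab == "cold"),
           "both a hot and a cold group are required")
    if (includeSum)
        scores <- cbind(scores, immune_related_sum = rowSums(scores))
    colMeans(scores[lab == "hot", , drop = FALSE]) -
        colMeans(scores[lab == "cold", , drop = FALSE])
}

#' Tumor mutational burden
#'
#' Non-synonymous mutation count per megabase of covered somatic genome.
#'
#' @param nonsynonymousMutationCount non-negative mutation count.
#' @param megabasesCovered covered megabases, > 0.
#' @return TMB in mutations per megabase.
#' @export
tmb <- function(nonsynonymousMutationCount, megabasesCovered) {
    stopIf(any(nonsynonymousMutationCount < 0), "mutation count must be >= 0")
    stopIf(any(megabasesCovered <= 0), "megabasesCovered must be > 0")
    nonsynonymousMutationCount / megabasesCovered
}
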