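#' Consensus clustering by subsampled hierarchical clustering
#'
#' Monti-style consensus clustering: for each repetition a fraction of the
#' samples is drawn without replacement and hierarchically clustered
#' (Euclidean distance, Ward linkage on unsquared distances, \code{"ward.D"})
#' into k groups. The consensus between two samples is the number of times
#' they co-clustered divided by the number of times they were co-sampled.
#' Final labels come from hierarchical clustering of 1 - consensus. The PAC
#' score (proportion of ambiguous clustering) is the fraction of off-diagonal
#' consensus entries strictly inside (0.1, 0.9).
#'
#' @param features samples x features numeric matrix with rownames.
#' @param k cluster count (2 <= k <= n/2).
#' @param reps subsampling repetitions (default 1000).
#' @param subsampleFraction fraction of samples drawn per repetition
#'   (default 0.8, without replacement).
#' @param seed integer seed; the run is deterministic for a fixed seed.
#' @return A \linkS4class{ConsensusResult}.
#' @export
consensusCluster <- function(features, k, reps = 1000,
                             subsampleFraction = 0.8, seed = 1L) {
    stopifnot(is.matrix(features), !is.null(rownames(features)))
    stopIf(any(!is.finite(features)), "features must be finite")
    n <- nrow(features)
    stopIf(k < 2 || k > n / 2, "k must satisfy 2 <= k <= n/2 (n = %d)", n)
    m <- max(k, floor(subsampleFraction * n))
    withSeed(seed, {
        co <- matrix(0, n, n)
        tog <- matrix(0, n, n)
        for (r in seq_len(reps)) {
            idx <- sort(sample.int(n, m))
            cl <- stats::cutree(stats::hclust(stats::dist(
                features[idx, , drop = FALSE]), method = "ward.D"), k = k)
            same <- outer(cl, cl, "==") + 0
            co[idx, idx] <- co[idx, idx] + same
            tog[idx, idx] <- tog[idx, idx] + 1
        }
        cons <- ifelse(tog > 0, co / pmax(tog, 1), 0)
        diag(cons) <- 1
        cons <- (cons + t(cons)) / 2
        dimnames(cons) <- list(rownames(features), rownames(features))
        labels <- stats::cutree(stats::hclust(stats::as.dist(1 - cons),
                                              method = "ward.D"), k = k)
        off <- cons[upper.tri(cons)]
        pac <- mean(off > 0.1 & off < 0.9)
        new("ConsensusResult", k = as.integer(k), consensusMatrix = cons,
            labels = stats::setNames(as.integer(labels), rownames(features)),
            pacScore = pac)
    })
}

#' Two-step immune subtype classifier
#'
#' Step 1: consensus clustering (k = 2) of the immune-cell fraction columns;
#' the cluster with the higher mean summed effector-cell fraction is the
#' immune-infiltrated A subtype, the other B. Step 2: consensus clustering
#' (k = 3) of the z-scored early differentiation signature expression of the
#' A samples only; the three clusters are named A1/A2/A3 by decreasing mean
#' effector fraction (A1 highest).
#'
#' Because full fraction rows live on the simplex (they always sum to 1),
#' infiltration is measured as the summed fraction of designated effector
#' cell types rather than of all columns.
#'
#' @param fractions a \linkS4class{CellFractions}.
#' @param expr an \linkS4class{ExpressionMatrix} sharing the sample ids.
#' @param earlyGenes early differentiation signature gene ids (>= 2 present
#'   in \code{expr}).
#' @param seed integer seed.
#' @param reps,subsampleFraction consensus-clustering parameters.
#' @param effectorTypes cell-type columns whose summed fraction measures
#'   immune infiltration.
#' @return Named character labels in \code{A1/A2/A3/B}; attributes
#'   \code{step1} and \code{step2} carry the \linkS4class{ConsensusResult}s.
#' @export
twoStepSubtype <- function(fractions, expr, earlyGenes, seed = 1L,
                           reps = 1000, subsampleFraction = 0.8,
                           effectorTypes = c("Macrophages.M1", "T.cells.CD8",
                               "T.cells.CD4.memory.activated")) {
    stopifnot(is(fractions, "CellFractions"), is(expr, "ExpressionMatrix"))
    F <- fractionValues(fractions)
    common <- intersect(rownames(F), sampleIds(expr))
    stopIf(length(common) < nrow(F), "fractions and expr must share sample ids")
    eff <- intersect(effectorTypes, colnames(F))
    stopIf(length(eff) == 0, "no effector cell-type columns found in fractions")
    genes <- intersect(earlyGenes, geneIds(expr))
    stopIf(length(genes) < 2, "need >= 2 early signature genes in expr")
    stopIf(all(apply(F, 2, stats::sd) == 0),
           "zero-variance input: all samples have identical fractions")

    effSum <- rowSums(F[, eff, drop = FALSE])
    cc1 <- consensusCluster(F, k = 2, reps = reps,
                            subsampleFraction = subsampleFraction, seed = seed)
    l1 <- clusterLabels(cc1)
    meansByCl <- tapply(effSum, l1, mean)
    aCluster <- as.integer(names(meansByCl)[which.max(meansByCl)])
    labels <- stats::setNames(rep("B", nrow(F)), rownames(F))
    aSamples <- names(l1)[l1 == aCluster]

    lv <- exprValues(asLogScale(expr))[genes, aSamples, drop = FALSE]
    sds <- apply(lv, 1, stats::sd)
    lv <- lv[sds > 0, , drop = FALSE]
    stopIf(nrow(lv) < 2, "zero-variance input: early signature genes are constant")
    z <- t((lv - rowMeans(lv)) / apply(lv, 1, stats::sd))
    cc2 <- consensusCluster(z, k = 3, reps = reps,
                            subsampleFraction = subsampleFraction,
                            seed = seed + 1L)
    l2 <- clusterLabels(cc2)
    sizes <- table(l2)
    if (any(sizes < 2)) {
        warning("step-2 cluster(s) with < 2 samples merged into the nearest cluster")
        small <- as.integer(names(sizes)[sizes < 2])
        big <- as.integer(names(sizes)[sizes >= 2])
        cent <- vapply(big, function(g)
            colMeans(z[l2 == g, , drop = FALSE]), numeric(ncol(z)))
        for (s in names(l2)[l2 %in% small]) {
            d <- colSums((cent - z[s, ])^2)
            l2[s] <- big[which.min(d)]
        }
    }
    effA <- tapply(effSum[aSamples], l2[aSamples], mean)
    ord <- names(sort(effA, decreasing = TRUE))
    rankOf <- stats::setNames(seq_along(ord), ord)
    labels[aSamples] <- paste0("A", rankOf[as.character(l2[aSamples])])
    attr(labels, "step1") <- cc1
    attr(labels, "step2") <- cc2
    labels
}

#' Two-group log-rank test with Kaplan-Meier step tables
#'
#' Standard log-rank statistic (observed minus expected events over the
#' pooled risk sets), chi-square with 1 degree of freedom, plus Kaplan-Meier
#' survival curves per group as step-function tables.
#'
#' @param surv data.frame with columns \code{sample}, \code{time} (> 0),
#'   \code{event} (0/1).
#' @param labels named two-group assignment covering the samples.
#' @return List with \code{chiSquare}, \code{pValue}, \code{observed},
#'   \code{expected} (per group), and \code{km} (data.frame group, time,
#'   nRisk, nEvent, survival).
#' @export
logrank <- function(surv, labels) {
    stopifnot(all(c("sample", "time", "event") %in% names(surv)))
    stopIf(any(surv$time <= 0) || any(!is.finite(surv$time)),
           "survival times must be positive and finite")
    g <- factor(labels[surv$sample])
    stopIf(nlevels(g) != 2 || any(table(g) == 0),
           "exactly two non-empty groups are required")
    stopIf(sum(surv$event) < 1, "at least one event is required")
    parts <- lapply(split(surv[c("time", "event")], g), function(d)
        d[order(d$time, d$event), , drop = FALSE])
    identicalGroups <- isTRUE(all.equal(parts[[1]]$time, parts[[2]]$time)) &&
        identical(parts[[1]]$event, parts[[2]]$event)
    if (identicalGroups) {
        # identical survival experience: observed = expected exactly
        obs <- tapply(surv$event, g, sum)
        sd0 <- list(obs = obs, exp = obs)
        chi <- 0
    } else {
        sd0 <- survival::survdiff(survival::Surv(time, event) ~ g,
                                  data = data.frame(surv, g = g))
        chi <- unname(sd0$chisq)
    }
    fit <- survival::survfit(survival::Surv(time, event) ~ g,
                             data = data.frame(surv, g = g))
    km <- data.frame(
        group = rep(levels(g), fit$strata),
        time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
        survival = fit$surv, stringsAsFactors = FALSE)
    list(chiSquare = chi,
         pValue = stats::pchisq(chi, df = 1, lower.tail = FALSE),
         observed = sd0$obs, expected = sd0$exp, km = km)
}
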