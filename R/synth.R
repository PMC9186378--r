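#' Configuration for the synthetic single-cell cohort generator
#'
#' Describes a population of cells along a monocyte-to-macrophage
#' differentiation axis: a uniform latent time on [0, 1], early marker genes
#' whose expected expression decreases with time, late markers that increase,
#' mitochondrial genes (named with an \code{MT-} prefix), and optional planted
#' copy-number segments carried by a subset of cells.
#'
#' @param nCells,nGenes cell and gene counts.
#' @param nMitoGenes number of mitochondrial (\code{MT-}) genes.
#' @param nEarlyMarkers,nLateMarkers marker gene counts.
#' @param earlyEffectLog2fc planted log2 fold change of the markers between
#'   the extremes of the differentiation axis; must exceed the signature
#'   threshold (1.3) so recovery is well-posed.
#' @param noiseSd standard deviation of extra per-cell-per-gene log2-scale
#'   noise, on top of the count model.
#' @param cnvSegments list of numeric triplets
#'   \code{c(gene_start_index, gene_end_index, multiplicative_shift)}.
#' @param countModel \code{"nb"} for negative-binomial counts (default;
#'   realistic QC statistics) or \code{"mean"} for deterministic expected
#'   values (noiseless gradients for trajectory work).
#' @param switchWidth width of the logistic early-to-late transition on the
#'   latent-time axis (default 0.1, a sharp switch between differentiation
#'   states; use ~0.5 for a gradual gradient along the whole axis).
#' @param seed integer seed; generation is bit-reproducible for a fixed seed.
#' @return A validated \code{ScSimConfig} list.
#' @export
scSimConfig <- function(nCells = 500, nGenes = 1000, nMitoGenes = 10,
                        nEarlyMarkers = 50, nLateMarkers = 50,
                        earlyEffectLog2fc = 2, noiseSd = 0.2,
                        cnvSegments = list(), countModel = c("nb", "mean"),
                        switchWidth = 0.1, seed = 1L) {
    countModel <- match.arg(countModel)
    stopIf(nEarlyMarkers + nLateMarkers + nMitoGenes > nGenes,
           "invalid ScSimConfig: nEarlyMarkers + nLateMarkers + nMitoGenes (%d) exceeds nGenes (%d)",
           nEarlyMarkers + nLateMarkers + nMitoGenes, nGenes)
    stopIf(earlyEffectLog2fc <= 1.3,
           "invalid ScSimConfig: earlyEffectLog2fc (%g) must exceed the signature threshold 1.3",
           earlyEffectLog2fc)
    stopIf(noiseSd < 0, "invalid ScSimConfig: noiseSd must be >= 0")
    for (seg in cnvSegments)
        stopIf(length(seg) != 3 || seg[1] < 1 || seg[2] > nGenes ||
               seg[1] > seg[2] || seg[3] <= 0,
               "invalid ScSimConfig: each cnvSegment must be c(start, end, shift>0) within 1..nGenes")
    structure(list(nCells = as.integer(nCells), nGenes = as.integer(nGenes),
                   nMitoGenes = as.integer(nMitoGenes),
                   nEarlyMarkers = as.integer(nEarlyMarkers),
                   nLateMarkers = as.integer(nLateMarkers),
                   earlyEffectLog2fc = earlyEffectLog2fc, noiseSd = noiseSd,
                   cnvSegments = cnvSegments, countModel = countModel,
                   switchWidth = switchWidth, seed = as.integer(seed)),
              class = "ScSimConfig")
}

#' Generate a synthetic single-cell cohort
#'
#' Cells sit at latent times t ~ U(0, 1). Marker effects follow a smooth
#' logistic transition centred at t = 0.5 (width 0.1), so the early third and
#' late third of the axis differ by the full planted log2 fold change. Counts
#' are negative-binomial around the log-mean structure; library-size and
#' mitochondrial-content outliers are planted so QC filtering is exercised.
#' CNV segments multiply the expected expression of half of the cells (the
#' aberrant set); the other half serve as reference.
#'
#' @param cfg an \code{\link{scSimConfig}}.
#' @return A list with elements \code{expr} (raw-count
#'   \linkS4class{ExpressionMatrix}), \code{latentTime} (named per cell),
#'   \code{earlyGenes}, \code{lateGenes}, \code{mitoGenes},
#'   \code{cnvProfile} (named per-gene planted log2 shift),
#'   \code{cnvCells} (ids of aberrant cells), \code{geneOrder}
#'   (BED-like data.frame placing genes on one synthetic chromosome),
#'   and \code{config}.
#' @export
genScCohort <- function(cfg) {
    stopifnot(inherits(cfg, "ScSimConfig"))
    withSeed(cfg$seed, {
        nG <- cfg$nGenes; nC <- cfg$nCells
        nMarkers <- cfg$nEarlyMarkers + cfg$nLateMarkers
        genes <- c(sprintf("EARLY%04d", seq_len(cfg$nEarlyMarkers)),
                   sprintf("LATE%04d", seq_len(cfg$nLateMarkers)),
                   sprintf("MT-%02d", seq_len(cfg$nMitoGenes)),
                   sprintf("G%05d", seq_len(nG - nMarkers - cfg$nMitoGenes)))
        cells <- sprintf("cell%04d", seq_len(nC))
        t <- stats::runif(nC)
        names(t) <- cells

        baseLog2 <- stats::runif(nG, 2, 5)              # per-gene baseline
        names(baseLog2) <- genes
        mito <- grep("^MT-", genes, value = TRUE)
        baseLog2[mito] <- stats::runif(length(mito), 4, 5.5)

        # smooth early->late switch; with the default width the early third
        # and late third of the axis differ by the full planted effect
        s <- stats::plogis((t - 0.5) / cfg$switchWidth)
        eff <- matrix(0, nG, nC, dimnames = list(genes, cells))
        early <- genes[seq_len(cfg$nEarlyMarkers)]
        late <- genes[cfg$nEarlyMarkers + seq_len(cfg$nLateMarkers)]
        eff[early, ] <- matrix(rep(cfg$earlyEffectLog2fc * (1 - s), each =
            length(early)), length(early), nC)
        eff[late, ] <- matrix(rep(cfg$earlyEffectLog2fc * s, each =
            length(late)), length(late), nC)

        # planted CNV: aberrant half of the cells, log2 shift per gene
        cnvProfile <- stats::setNames(numeric(nG), genes)
        for (seg in cfg$cnvSegments)
            cnvProfile[seg[1]:seg[2]] <- cnvProfile[seg[1]:seg[2]] + log2(seg[3])
        cnvCells <- cells[seq_len(nC) %% 2L == 0L]
        eff[, cnvCells] <- eff[, cnvCells] + cnvProfile

        # per-cell depth factors; under the count model a few shallow cells
        # fall below the 200-detected-genes QC floor and ~8% of cells carry
        # a high mitochondrial load (the "mean" model is an idealized
        # gradient and plants no QC outliers)
        depth <- rep(1, nC)
        mitoFactor <- rep(1, nC)
        if (cfg$countModel == "nb") {
            depth <- 2^stats::rnorm(nC, 0, 0.15)
            depth[seq_len(max(1L, round(0.03 * nC)))] <- 0.002
            highMito <- nC - seq_len(max(1L, round(0.08 * nC))) + 1L
            mitoFactor[highMito] <- 8
        }
        eff[mito, ] <- sweep(eff[mito, , drop = FALSE], 2, log2(mitoFactor), "+")

        log2mu <- baseLog2 + eff
        log2mu <- sweep(log2mu, 2, log2(depth), "+")
        if (cfg$noiseSd > 0)
            log2mu <- log2mu + matrix(stats::rnorm(nG * nC, 0, cfg$noiseSd),
                                      nG, nC)
        mu <- 2^log2mu
        counts <- if (cfg$countModel == "nb")
            matrix(stats::rnbinom(nG * nC, mu = mu, size = 10), nG, nC,
                   dimnames = dimnames(mu))
        else round(mu, 6)
        # a handful of near-absent genes exercise the min-cells-per-gene rule
        rare <- grep("^G", genes)[1:5]
        counts[rare, ] <- 0
        counts[rare, 1:2] <- 1
        dimnames(counts) <- list(genes, cells)

        geneOrder <- data.frame(chrom = "chr1",
                                start = seq_len(nG) * 1000L,
                                end = seq_len(nG) * 1000L + 500L,
                                gene = genes, stringsAsFactors = FALSE)
        list(expr = ExpressionMatrix(counts), latentTime = t,
             earlyGenes = early, lateGenes = late, mitoGenes = mito,
             cnvProfile = cnvProfile, cnvCells = cnvCells,
             geneOrder = geneOrder, config = cfg)
    })
}

#' Configuration for the synthetic bulk cohort generator
#'
#' Bulk samples are mixtures of immune-cell reference profiles with a planted
#' chemokine-driven hot/cold phenotype, exponential survival times whose
#' hazard differs between hot and cold, and ICB response labels drawn from a
#' logistic model on the seven predictor features (four chemokine levels and
#' three effector-cell fractions).
#'
#' @param nSamples sample count.
#' @param nCellTypes number of reference cell types (default 22, LM22-style).
#' @param basis optional genes x cell-types non-negative reference matrix;
#'   generated (with marker-block structure) when \code{NULL}.
#' @param nGenes gene count for a generated basis.
#' @param hotFraction fraction of samples planted immune-hot.
#' @param chemokineGenes the four chemokine gene ids.
#' @param hotEffectLog2fc planted log2 fold change of chemokine expression in
#'   hot samples.
#' @param survivalHazardRatioHotVsCold hazard ratio (hot vs cold) of the
#'   exponential survival model.
#' @param responseCoefficients numeric length 8: intercept then 7 feature
#'   coefficients of the logistic response model (features z-scored:
#'   log2 chemokine levels of CXCL9/10/11, CCL5 order as given, then the
#'   effector fractions).
#' @param effectorTypes the three effector cell-type names used for the
#'   response features and the hot-sample composition shift.
#' @param noiseSd sd of additive expression noise (values clamped at 0).
#' @param plantSubtypes plant a four-subtype structure (A1/A2/A3/B): A
#'   samples (the hot fraction) carry graded effector-cell infiltration
#'   (A1 > A2 > A3 > B) and subtype-specific blocks of early-signature genes
#'   are shifted by \code{subtypeEffectLog2fc}; B samples are the cold ones.
#' @param nEarlySignatureGenes number of planted early-signature genes
#'   (3 blocks; used when \code{plantSubtypes}).
#' @param subtypeEffectLog2fc log2 shift of a subtype's early-signature
#'   block.
#' @param seed integer seed.
#' @return A validated \code{BulkSimConfig} list.
#' @export
bulkSimConfig <- function(nSamples = 200, nCellTypes = 22, basis = NULL,
                          nGenes = 400, hotFraction = 0.5,
                          chemokineGenes = c("CXCL9", "CXCL10", "CXCL11", "CCL5"),
                          hotEffectLog2fc = 2,
                          survivalHazardRatioHotVsCold = 0.4,
                          responseCoefficients = c(-0.5, 1, 1, 1, 1, 0.8, 0.8, 0.8),
                          effectorTypes = c("Macrophages.M1", "T.cells.CD8",
                                            "T.cells.CD4.memory.activated"),
                          noiseSd = 0.1, plantSubtypes = FALSE,
                          nEarlySignatureGenes = 30, subtypeEffectLog2fc = 2,
                          seed = 1L) {
    stopIf(length(chemokineGenes) != 4, "invalid BulkSimConfig: need 4 chemokine genes")
    stopIf(hotFraction <= 0 || hotFraction >= 1,
           "invalid BulkSimConfig: hotFraction must lie in (0,1)")
    stopIf(length(responseCoefficients) != 8,
           "invalid BulkSimConfig: responseCoefficients must be intercept + 7 values")
    stopIf(survivalHazardRatioHotVsCold <= 0,
           "invalid BulkSimConfig: hazard ratio must be > 0")
    stopIf(noiseSd < 0, "invalid BulkSimConfig: noiseSd must be >= 0")
    if (!is.null(basis)) {
        stopIf(any(basis < 0), "invalid BulkSimConfig: basis must be non-negative")
        stopIf(qr(basis)$rank < ncol(basis),
               "invalid BulkSimConfig: basis columns must be linearly independent")
    }
    structure(list(nSamples = as.integer(nSamples),
                   nCellTypes = as.integer(nCellTypes), basis = basis,
                   nGenes = as.integer(nGenes), hotFraction = hotFraction,
                   chemokineGenes = chemokineGenes,
                   hotEffectLog2fc = hotEffectLog2fc,
                   survivalHazardRatioHotVsCold = survivalHazardRatioHotVsCold,
                   responseCoefficients = responseCoefficients,
                   effectorTypes = effectorTypes, noiseSd = noiseSd,
                   plantSubtypes = isTRUE(plantSubtypes),
                   nEarlySignatureGenes = as.integer(nEarlySignatureGenes),
                   subtypeEffectLog2fc = subtypeEffectLog2fc,
                   seed = as.integer(seed)),
              class = "BulkSimConfig")
}

# LM22-flavoured cell-type names, extended/truncated to n
.cellTypeNames <- function(n, effectorTypes) {
    base <- c(effectorTypes, "B.cells.naive", "B.cells.memory", "Plasma.cells",
              "T.cells.CD4.naive", "T.cells.CD4.memory.resting",
              "T.cells.follicular.helper", "T.cells.regulatory",
              "T.cells.gamma.delta", "NK.cells.resting", "NK.cells.activated",
              "Monocytes", "Macrophages.M0", "Macrophages.M2",
              "Dendritic.cells.resting", "Dendritic.cells.activated",
              "Mast.cells.resting", "Mast.cells.activated", "Eosinophils",
              "Neutrophils")
    if (n <= length(base)) base[seq_len(n)]
    else c(base, sprintf("Cell.type.%02d", seq_len(n - length(base))))
}

# marker-block reference basis; chemokines load on the effector types
.makeBasis <- function(nGenes, types, chemokineGenes, effectorTypes) {
    nT <- length(types)
    genes <- c(chemokineGenes,
               sprintf("BG%04d", seq_len(nGenes - length(chemokineGenes))))
    B <- matrix(stats::rexp(nGenes * nT, rate = 2), nGenes, nT,
                dimnames = list(genes, types))
    per <- max(3L, (nGenes - length(chemokineGenes)) %/% nT)
    for (j in seq_len(nT)) {
        rows <- length(chemokineGenes) + ((j - 1L) * per + 1L):(j * per)
        rows <- rows[rows <= nGenes]
        B[rows, j] <- B[rows, j] + 8
    }
    B[chemokineGenes, ] <- 0.3
    B[chemokineGenes, effectorTypes] <- 4
    B
}

#' Generate a synthetic bulk cohort
#'
#' Expression = basis x fractions, with chemokine rows of hot samples
#' multiplied by \code{2^hotEffectLog2fc}, plus additive Gaussian noise.
#' Fractions are Dirichlet draws; hot samples receive a higher concentration
#' on the effector types so infiltration tracks the phenotype. Survival is
#' exponential with the configured hot-vs-cold hazard ratio and ~25%
#' administrative censoring; response labels are Bernoulli under the logistic
#' model on the seven (z-scored) predictor features.
#'
#' @param cfg a \code{\link{bulkSimConfig}}.
#' @return A list with \code{expr} (linear-scale
#'   \linkS4class{ExpressionMatrix}), \code{fractions} (true
#'   \linkS4class{CellFractions}), \code{hotLabels} (named
#'   \code{"hot"}/\code{"cold"}), \code{subtypeLabels} (named A1/A2/A3/B,
#'   when \code{plantSubtypes}), \code{earlySignatureGenes}, \code{survival}
#'   (data.frame sample, time, event), \code{response} (named 0/1),
#'   \code{basis}, \code{features} (the 7 generative predictor values per
#'   sample), and \code{config}.
#' @export
genBulkCohort <- function(cfg) {
    stopifnot(inherits(cfg, "BulkSimConfig"))
    withSeed(cfg$seed, {
        types <- if (!is.null(cfg$basis)) colnames(cfg$basis)
                 else .cellTypeNames(cfg$nCellTypes, cfg$effectorTypes)
        B <- if (!is.null(cfg$basis)) cfg$basis
             else .makeBasis(cfg$nGenes, types, cfg$chemokineGenes,
                             cfg$effectorTypes)
        stopIf(qr(B)$rank < ncol(B), "singular basis: columns are linearly dependent")
        nS <- cfg$nSamples
        samples <- sprintf("S%04d", seq_len(nS))
        nHot <- round(cfg$hotFraction * nS)
        hot <- stats::setNames(rep("cold", nS), samples)
        hot[sample(samples, nHot)] <- "hot"
        eff <- intersect(cfg$effectorTypes, types)

        subtype <- NULL
        alpha <- matrix(1, nS, ncol(B), dimnames = list(samples, types))
        if (cfg$plantSubtypes) {
            # hot samples split evenly into A1/A2/A3 with graded effector
            # infiltration (A1 highest); cold samples are B
            subtype <- stats::setNames(rep("B", nS), samples)
            hotIds <- names(hot)[hot == "hot"]
            subtype[hotIds] <- rep(c("A1", "A2", "A3"),
                                   length.out = length(hotIds))
            effAlpha <- c(A1 = 12, A2 = 7, A3 = 4.5, B = 1)
            alpha[, eff] <- effAlpha[subtype]
        } else {
            alpha[hot == "hot", eff] <- 4
        }
        F <- t(apply(alpha, 1, function(a) {
            g <- stats::rgamma(length(a), shape = a, rate = 1)
            g / sum(g)
        }))
        dimnames(F) <- list(samples, types)

        expr <- B %*% t(F)
        earlyGenes <- character()
        if (cfg$plantSubtypes) {
            # three blocks of early-signature genes, one up-shifted block
            # per A subtype; B keeps the baseline
            nE <- cfg$nEarlySignatureGenes
            earlyGenes <- sprintf("EARLYSIG%03d", seq_len(nE))
            base <- matrix(2^stats::runif(nE * nS, 1, 2), nE, nS,
                           dimnames = list(earlyGenes, samples))
            block <- rep(1:3, length.out = nE)
            for (j in 1:3) {
                sel <- subtype == paste0("A", j)
                base[block == j, sel] <- base[block == j, sel] *
                    2^cfg$subtypeEffectLog2fc
            }
            expr <- rbind(expr, base)
        }
        chem <- intersect(cfg$chemokineGenes, rownames(expr))
        expr[chem, hot == "hot"] <- expr[chem, hot == "hot"] *
            2^cfg$hotEffectLog2fc
        if (cfg$noiseSd > 0)
            expr <- pmax(expr + matrix(stats::rnorm(length(expr), 0,
                cfg$noiseSd), nrow(expr), ncol(expr)), 0)

        # survival: exponential, hazard ratio hot vs cold, admin censoring
        h0 <- 0.1
        rate <- ifelse(hot == "hot", h0 * cfg$survivalHazardRatioHotVsCold, h0)
        tEvent <- stats::rexp(nS, rate = rate)
        cens <- stats::quantile(tEvent, 0.75)
        surv <- data.frame(sample = samples,
                           time = pmin(tEvent, cens) + 1e-9,
                           event = as.integer(tEvent <= cens),
                           stringsAsFactors = FALSE)

        # logistic response model on the 7 generative features
        feat <- cbind(t(log2(expr[chem, , drop = FALSE] + 1)),
                      F[, intersect(cfg$effectorTypes, types), drop = FALSE])
        fz <- scale(feat)
        eta <- cfg$responseCoefficients[1] +
            as.vector(fz %*% cfg$responseCoefficients[-1])
        response <- stats::setNames(
            stats::rbinom(nS, 1, stats::plogis(eta)), samples)

        list(expr = ExpressionMatrix(expr), fractions = CellFractions(F),
             hotLabels = hot, subtypeLabels = subtype,
             earlySignatureGenes = earlyGenes, survival = surv,
             response = response, basis = B, features = feat, config = cfg)
    })
}

#' Configuration for the synthetic interaction-graph generator
#'
#' An Erdos-Renyi background with one planted, internally denser module —
#' the stand-in for a protein-interaction network containing hub genes.
#'
#' @param nBackgroundNodes total node count.
#' @param backgroundEdgeProbability edge probability outside the module.
#' @param plantedModuleSize,plantedModuleDensity module size and its internal
#'   edge probability; the density must exceed the background probability.
#' @param moduleBackgroundMultiplier factor on the background probability for
#'   edges between module and non-module nodes (default 3): hub modules are
#'   globally central, not merely internally dense.
#' @param seed integer seed.
#' @return A validated \code{GraphSimConfig} list.
#' @export
graphSimConfig <- function(nBackgroundNodes = 200,
                           backgroundEdgeProbability = 0.02,
                           plantedModuleSize = 12,
                           plantedModuleDensity = 1.0,
                           moduleBackgroundMultiplier = 3, seed = 1L) {
    stopIf(plantedModuleDensity <= backgroundEdgeProbability,
           "invalid GraphSimConfig: plantedModuleDensity (%g) must exceed backgroundEdgeProbability (%g)",
           plantedModuleDensity, backgroundEdgeProbability)
    stopIf(plantedModuleSize > nBackgroundNodes,
           "invalid GraphSimConfig: module larger than the graph")
    stopIf(backgroundEdgeProbability <= 0 || backgroundEdgeProbability >= 1,
           "invalid GraphSimConfig: backgroundEdgeProbability must lie in (0,1)")
    stopIf(moduleBackgroundMultiplier < 1,
           "invalid GraphSimConfig: moduleBackgroundMultiplier must be >= 1")
    structure(list(nBackgroundNodes = as.integer(nBackgroundNodes),
                   backgroundEdgeProbability = backgroundEdgeProbability,
                   plantedModuleSize = as.integer(plantedModuleSize),
                   plantedModuleDensity = plantedModuleDensity,
                   moduleBackgroundMultiplier = moduleBackgroundMultiplier,
                   seed = as.integer(seed)),
              class = "GraphSimConfig")
}

#' Generate a synthetic interaction graph with a planted dense module
#'
#' @param cfg a \code{\link{graphSimConfig}}.
#' @return A list with \code{edges} (data.frame \code{from}, \code{to}),
#'   \code{nodes} (all node ids), \code{moduleIds} (the planted module), and
#'   \code{config}. The graph is simple and undirected; each unordered pair
#'   appears at most once with \code{from < to}.
#' @export
genPpi <- function(cfg) {
    stopifnot(inherits(cfg, "GraphSimConfig"))
    withSeed(cfg$seed, {
        n <- cfg$nBackgroundNodes
        nodes <- sprintf("G%03d", seq_len(n))
        moduleIds <- sort(sample(nodes, cfg$plantedModuleSize))
        pairs <- t(utils::combn(nodes, 2))
        inModule <- pairs[, 1] %in% moduleIds & pairs[, 2] %in% moduleIds
        halfModule <- xor(pairs[, 1] %in% moduleIds, pairs[, 2] %in% moduleIds)
        p <- ifelse(inModule, cfg$plantedModuleDensity,
                    ifelse(halfModule,
                           pmin(cfg$backgroundEdgeProbability *
                                cfg$moduleBackgroundMultiplier, 1),
                           cfg$backgroundEdgeProbability))
        keep <- stats::runif(nrow(pairs)) < p
        edges <- data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                            stringsAsFactors = FALSE)
        list(edges = edges, nodes = nodes, moduleIds = moduleIds, config = cfg)
    })
}
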