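#' Diffusion-map embedding of cells
#'
#' Differentiating cells are modelled as following noisy diffusion-like
#' dynamics: a Gaussian kernel with local bandwidth (the distance to the
#' \code{ceiling(nNeighbors/2)}-th neighbour) is evaluated on the
#' symmetrized kNN graph, row-normalized into a transition operator, and the
#' top non-trivial right eigenvectors, scaled by their eigenvalues, give the
#' embedding coordinates.
#'
#' @param expr an \linkS4class{ExpressionMatrix} (log2(x+1) applied if on
#'   linear scale); cells are columns.
#' @param nComponents number of diffusion components (default 3).
#' @param nNeighbors kNN graph size (default 15); needs
#'   \code{nCells >= nNeighbors + 1}.
#' @return List with \code{cellIds}, \code{coordinates} (cells x
#'   nComponents), \code{eigenvalues} (decreasing, in (0, 1]), and
#'   \code{stationary} (the stationary distribution of the transition
#'   operator, under which the components are orthogonal).
#' @export
diffusionMap <- function(expr, nComponents = 3, nNeighbors = 15) {
    stopifnot(is(expr, "ExpressionMatrix"))
    X <- t(exprValues(asLogScale(expr)))
    n <- nrow(X)
    stopIf(n < nNeighbors + 1, "need >= nNeighbors + 1 cells (%d < %d)",
           n, nNeighbors + 1)
    D <- as.matrix(stats::dist(X))

    knn <- t(apply(D, 1, function(d) order(d)[2:(nNeighbors + 1)]))
    sigma <- vapply(seq_len(n), function(i)
        D[i, knn[i, ceiling(nNeighbors / 2)]], numeric(1))
    sigma[sigma == 0] <- max(min(D[D > 0]), 1e-12)

    mask <- matrix(FALSE, n, n)
    for (i in seq_len(n)) mask[i, knn[i, ]] <- TRUE
    mask <- mask | t(mask)

    # connectivity of the kNN graph
    seen <- logical(n); seen[1] <- TRUE; frontier <- 1L
    while (length(frontier)) {
        nxt <- which(colSums(mask[frontier, , drop = FALSE]) > 0 & !seen)
        seen[nxt] <- TRUE
        frontier <- nxt
    }
    stopIf(!all(seen),
           "kNN graph is disconnected; increase nNeighbors (currently %d)",
           nNeighbors)

    K <- matrix(0, n, n)
    sij <- outer(sigma, sigma)
    K[mask] <- exp(-(D[mask]^2) / sij[mask])
    diag(K) <- 1
    K <- (K + t(K)) / 2
    d <- rowSums(K)
    S <- K / sqrt(outer(d, d))
    eig <- eigen(S, symmetric = TRUE)
    lam <- eig$values[-1]
    keep <- which(lam > 1e-12)[seq_len(min(nComponents, sum(lam > 1e-12)))]
    psi <- eig$vectors[, -1, drop = FALSE][, keep, drop = FALSE] / sqrt(d)
    lam <- pmin(lam[keep], 1)
    # weight components by lambda/(1 - lambda): the aggregate diffusion
    # distance over all diffusion times, which damps higher harmonics
    coords <- sweep(psi, 2, pmin(lam, 1 - 1e-9) / (1 - pmin(lam, 1 - 1e-9)),
                    "*")
    # canonical sign: largest-magnitude entry positive
    for (k in seq_len(ncol(coords))) {
        i <- which.max(abs(coords[, k]))
        if (coords[i, k] < 0) coords[, k] <- -coords[, k]
    }
    dimnames(coords) <- list(rownames(X),
                             sprintf("DC%d", seq_len(ncol(coords))))
    list(cellIds = rownames(X), coordinates = coords, eigenvalues = lam,
         stationary = stats::setNames(d / sum(d), rownames(X)))
}

#' Pseudotime from a diffusion embedding
#'
#' Euclidean distance from the root cell in diffusion coordinates, min-max
#' rescaled to [0, 1] (root at 0).
#'
#' @param emb output of \code{\link{diffusionMap}}.
#' @param root cell id of the trajectory root (e.g. the monocyte end).
#' @return List with \code{time} (named, in [0, 1]) and \code{rootCellId}.
#' @export
pseudotime <- function(emb, root) {
    stopIf(!root %in% emb$cellIds, "unknown root cell '%s'", root)
    C <- emb$coordinates
    dif <- sweep(C, 2, C[root, ], "-")
    t <- sqrt(rowSums(dif^2))
    if (max(t) > 0) t <- t / max(t)
    list(time = stats::setNames(t, emb$cellIds), rootCellId = root)
}

#' Gene expression trends along pseudotime
#'
#' Spearman rank correlation of each gene with pseudotime, with asymptotic
#' p-values and Benjamini-Hochberg FDR. Constant genes are reported with
#' rho = 0 and flagged.
#'
#' @param expr an \linkS4class{ExpressionMatrix} containing the cells of
#'   \code{pt}.
#' @param pt output of \code{\link{pseudotime}}.
#' @param geneIds genes to test (default: all genes in \code{expr}).
#' @return data.frame with columns \code{gene}, \code{rho}, \code{p},
#'   \code{fdr}, \code{constant}.
#' @export
expressionAlongPseudotime <- function(expr, pt, geneIds = NULL) {
    stopifnot(is(expr, "ExpressionMatrix"))
    v <- exprValues(expr)
    if (is.null(geneIds)) geneIds <- rownames(v)
    missing <- setdiff(geneIds, rownames(v))
    stopIf(length(missing) > 0, "genes not present: %s",
           paste(utils::head(missing, 5), collapse = ", "))
    tm <- pt$time[colnames(v)]
    stopIf(any(is.na(tm)), "pseudotime missing for some cells")
    res <- lapply(geneIds, function(g) {
        x <- v[g, ]
        if (stats::sd(x) == 0)
            return(data.frame(gene = g, rho = 0, p = 1, constant = TRUE))
        ct <- suppressWarnings(stats::cor.test(x, tm, method = "spearman",
                                               exact = FALSE))
        data.frame(gene = g, rho = unname(ct$estimate), p = ct$p.value,
                   constant = FALSE)
    })
    out <- do.call(rbind, res)
    out$fdr <- stats::p.adjust(out$p, method = "BH")
    out[, c("gene", "rho", "p", "fdr", "constant")]
}
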