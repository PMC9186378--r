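# adjacency list from an edge data.frame; validates simplicity
.adjacency <- function(edges, nodes = NULL) {
    stopifnot(all(c("from", "to") %in% names(edges)))
    stopIf(any(edges$from == edges$to), "self-loops are not allowed")
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    stopIf(anyDuplicated(key) > 0, "multi-edges are not allowed")
    nodes <- sort(unique(c(nodes, edges$from, edges$to)))
    stopIf(length(nodes) == 0, "empty graph")
    idx <- stats::setNames(seq_along(nodes), nodes)
    adj <- vector("list", length(nodes))
    for (i in seq_len(nrow(edges))) {
        a <- idx[[edges$from[i]]]; b <- idx[[edges$to[i]]]
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
    }
    list(nodes = nodes, adj = adj)
}

# Brandes accumulation from one source; returns list(dist, sigma, delta)
.brandesFromSource <- function(adj, s) {
    n <- length(adj)
    dist <- rep(-1L, n); sigma <- numeric(n); delta <- numeric(n)
    dist[s] <- 0L; sigma[s] <- 1
    queue <- integer(n); qh <- 1L; qt <- 1L; queue[1] <- s
    order <- integer(0)
    while (qh <= qt) {
        v <- queue[qh]; qh <- qh + 1L
        order <- c(order, v)
        for (w in adj[[v]]) {
            if (dist[w] < 0L) {
                dist[w] <- dist[v] + 1L
                qt <- qt + 1L; queue[qt] <- w
            }
            if (dist[w] == dist[v] + 1L) sigma[w] <- sigma[w] + sigma[v]
        }
    }
    for (w in rev(order)) {
        for (v in adj[[w]]) if (dist[v] == dist[w] - 1L)
            delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
    }
    delta[s] <- 0   # dependencies accumulate only on non-source nodes
    list(dist = dist, delta = delta, source = s)
}

#' Node centralities of an undirected simple graph
#'
#' Computes, per node: degree (neighbour count); shortest-path betweenness
#' (sum over unordered pairs s, t distinct from v of the fraction of
#' s-t shortest paths passing through v; unnormalized, endpoint-excluding,
#' unreachable pairs skipped); eigenvector centrality (principal eigenvector
#' of the adjacency matrix by power iteration, tolerance 1e-10, non-negative,
#' unit Euclidean norm); and eccentricity centrality (reciprocal of the
#' longest shortest-path distance to any reachable node; 0 for isolated
#' nodes).
#'
#' @param edges data.frame with columns \code{from}, \code{to}.
#' @param nodes optional character vector of node ids (to include isolated
#'   nodes).
#' @return data.frame with columns \code{node}, \code{degree},
#'   \code{betweenness}, \code{eigenvector}, \code{eccentricity}; attribute
#'   \code{"lambda"} holds the dominant adjacency eigenvalue.
#' @export
centralities <- function(edges, nodes = NULL) {
    g <- .adjacency(edges, nodes)
    n <- length(g$nodes)
    degree <- vapply(g$adj, length, integer(1))

    btw <- numeric(n)
    ecc <- numeric(n)
    for (s in seq_len(n)) {
        bs <- .brandesFromSource(g$adj, s)
        btw <- btw + bs$delta
        reach <- bs$dist[bs$dist > 0L]
        ecc[s] <- if (length(reach)) 1 / max(reach) else 0
    }
    btw <- btw / 2   # unordered pairs counted once

    # power iteration on A + I for the principal adjacency eigenvector;
    # the shift breaks the +/- eigenvalue symmetry of bipartite graphs so
    # the iteration converges, and leaves the eigenvector unchanged
    x <- rep(1 / sqrt(n), n)
    lambda <- 0
    if (any(degree > 0)) {
        for (it in seq_len(100000)) {
            y <- x + vapply(seq_len(n), function(v) sum(x[g$adj[[v]]]),
                            numeric(1))
            nrm <- sqrt(sum(y^2))
            if (nrm == 0) { x <- rep(0, n); break }
            y <- y / nrm
            lambda <- nrm - 1
            if (max(abs(y - x)) < 1e-10) { x <- y; break }
            x <- y
        }
        x <- abs(x)
        x <- x / sqrt(sum(x^2))
    } else x <- rep(0, n)

    out <- data.frame(node = g$nodes, degree = as.integer(degree),
                      betweenness = btw, eigenvector = x,
                      eccentricity = ecc, stringsAsFactors = FALSE,
                      row.names = NULL)
    attr(out, "lambda") <- lambda
    out
}

#' Top-degree then top-secondary intersection hub screen
#'
#' Takes the \code{nDegree} nodes with the highest degree; within them,
#' ranks by each of two secondary centralities (eigenvector and betweenness
#' by default) and intersects the two top-\code{nSecondary} lists to give
#' the hub set. Ties at list boundaries are broken by the higher secondary
#' metric value and then lexicographic node id, and are flagged in the
#' audit.
#'
#' @param table a centrality table from \code{\link{centralities}}.
#' @param nDegree size of the degree pre-selection (default 40).
#' @param nSecondary size of each secondary list (default 20).
#' @param secondaryMetrics two column names of \code{table} used as the
#'   secondary metrics (eccentricity may be substituted).
#' @return List with \code{hubs} (sorted gene-id set) and \code{audit}
#'   (the three ranked tables plus tie flags).
#' @export
hubScreen <- function(table, nDegree = 40, nSecondary = 20,
                      secondaryMetrics = c("eigenvector", "betweenness")) {
    stopIf(nSecondary > nDegree, "nSecondary must be <= nDegree")
    stopIf(nrow(table) < nDegree,
           "need >= %d nodes, got %d", nDegree, nrow(table))
    stopifnot(all(secondaryMetrics %in% names(table)),
              length(secondaryMetrics) == 2)
    m1 <- secondaryMetrics[1]; m2 <- secondaryMetrics[2]

    ordDeg <- order(-table$degree, -table[[m1]], table$node)
    degRanked <- table[ordDeg, , drop = FALSE]
    fullTie <- length(unique(table$degree)) == 1
    boundaryTieDeg <- nrow(table) > nDegree &&
        degRanked$degree[nDegree] == degRanked$degree[nDegree + 1]
    top <- degRanked[seq_len(nDegree), , drop = FALSE]

    rankBy <- function(metric) {
        o <- order(-top[[metric]], top$node)
        r <- top[o, , drop = FALSE]
        tie <- nDegree > nSecondary &&
            r[[metric]][nSecondary] == r[[metric]][nSecondary + 1]
        list(ranked = r, boundaryTie = tie,
             top = r$node[seq_len(min(nSecondary, nrow(r)))])
    }
    r1 <- rankBy(m1)
    r2 <- rankBy(m2)
    list(hubs = sort(intersect(r1$top, r2$top)),
         audit = list(degreeRanked = degRanked,
                      secondaryRanked = stats::setNames(
                          list(r1$ranked, r2$ranked), secondaryMetrics),
                      boundaryTies = c(degree = boundaryTieDeg,
                          stats::setNames(c(r1$boundaryTie, r2$boundaryTie),
                                          secondaryMetrics)),
                      fullTie = fullTie))
}

#' Filter nodes by a strict degree threshold
#'
#' @param table a centrality table from \code{\link{centralities}}.
#' @param minDegree nodes with degree strictly greater are returned
#'   (default 30).
#' @return Character vector of node ids.
#' @export
degreeFilter <- function(table, minDegree = 30) {
    if (nrow(table) == 0) return(character())
    table$node[table$degree > minDegree]
}
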