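# Independent brute-force oracles used across the suite. These deliberately
# take different computational routes than the package implementations.

# small expression matrix fixture
makeExpr <- function(values, genes = NULL, cells = NULL, isLog = FALSE) {
    if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(values)))
    if (is.null(cells)) cells <- sprintf("c%02d", seq_len(ncol(values)))
    dimnames(values) <- list(genes, cells)
    ExpressionMatrix(values, isLog = isLog)
}

# ssGSEA oracle: closed-form position-weight sum instead of a running sum.
# ES = sum_{g in S} (w_g / W) (N - pos_g + 1) - sum_{g not in S} (N - pos_g + 1) / (N - |S|)
oracleSsgseaSample <- function(x, set, alpha) {
    r <- rank(x, ties.method = "average")
    ord <- order(r, decreasing = TRUE)   # same walk-order convention
    pos <- integer(length(x)); pos[ord] <- seq_along(x)
    inS <- names(x) %in% set
    w <- r^alpha
    N <- length(x)
    sum((w[inS] / sum(w[inS])) * (N - pos[inS] + 1)) -
        if (N > sum(inS)) sum((N - pos[!inS] + 1) / (N - sum(inS))) else 0
}

# all simple paths between s and t (node indices), tiny graphs only
.allPaths <- function(adj, s, t) {
    out <- list()
    recur <- function(path) {
        v <- path[length(path)]
        if (v == t) { out[[length(out) + 1]] <<- path; return(invisible()) }
        for (w in adj[[v]]) if (!(w %in% path)) recur(c(path, w))
    }
    recur(s)
    out
}

# betweenness by exhaustive shortest-path enumeration (n <= 8)
oracleBetweenness <- function(edges, nodes) {
    idx <- stats::setNames(seq_along(nodes), nodes)
    adj <- vector("list", length(nodes))
    for (i in seq_len(nrow(edges))) {
        a <- idx[[edges$from[i]]]; b <- idx[[edges$to[i]]]
        adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    n <- length(nodes)
    btw <- numeric(n)
    for (s in seq_len(n - 1)) for (t in seq((s + 1), n)) {
        paths <- .allPaths(adj, s, t)
        if (length(paths) == 0) next
        lens <- vapply(paths, length, integer(1))
        shortest <- paths[lens == min(lens)]
        sigma <- length(shortest)
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            through <- sum(vapply(shortest, function(p) v %in% p, logical(1)))
            btw[v] <- btw[v] + through / sigma
        }
    }
    stats::setNames(btw, nodes)
}

# all-pairs shortest distances by Floyd-Warshall
oracleDistances <- function(edges, nodes) {
    n <- length(nodes)
    idx <- stats::setNames(seq_len(n), nodes)
    D <- matrix(Inf, n, n); diag(D) <- 0
    for (i in seq_len(nrow(edges))) {
        a <- idx[[edges$from[i]]]; b <- idx[[edges$to[i]]]
        D[a, b] <- D[b, a] <- 1
    }
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    dimnames(D) <- list(nodes, nodes)
    D
}

# random simple graph on <= maxN nodes
randomSmallGraph <- function(maxN = 8) {
    n <- sample(3:maxN, 1)
    nodes <- sprintf("n%d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < 0.45
    if (!any(keep)) keep[sample(nrow(pairs), 2)] <- TRUE
    list(edges = data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                            stringsAsFactors = FALSE), nodes = nodes)
}

# Benjamini-Hochberg by the literal step-up definition
oracleBH <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- numeric(n)
    running <- 1
    for (i in seq(n, 1)) {
        running <- min(running, p[o[i]] * n / i)
        adj[o[i]] <- running
    }
    adj
}

# two-group log-rank chi-square from an explicit risk table
oracleLogrank <- function(time, event, group) {
    tms <- sort(unique(time[event == 1]))
    O1 <- E1 <- V <- 0
    for (tt in tms) {
        atRisk <- time >= tt
        n1 <- sum(atRisk & group == levels(factor(group))[1])
        n <- sum(atRisk)
        d <- sum(time == tt & event == 1)
        d1 <- sum(time == tt & event == 1 & group == levels(factor(group))[1])
        O1 <- O1 + d1
        E1 <- E1 + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    (O1 - E1)^2 / V
}

# AUC by exhaustive positive/negative pair comparison (ties half-weighted)
oracleAuc <- function(p, y) {
    pos <- p[y == 1]; neg <- p[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
        tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
}

# windowed mean oracle for the CNV profile: literal per-position loop
oracleWindowMean <- function(E, chrom, halfWindow) {
    out <- matrix(NA_real_, ncol(E), nrow(E),
                  dimnames = list(colnames(E), rownames(E)))
    for (k in seq_len(ncol(E))) for (i in seq_len(nrow(E))) {
        idx <- which(chrom == chrom[i] &
                     abs(seq_len(nrow(E)) - i) <= halfWindow)
        out[k, i] <- mean(E[idx, k])
    }
    out
}
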