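# adjusted Rand index between two labelings
ari <- function(a, b) {
    tab <- table(a, b)
    sumij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
    n2 <- choose(length(a), 2)
    (sumij - ai * bj / n2) / ((ai + bj) / 2 - ai * bj / n2)
}

test_that("consensus clustering resolves two point masses exactly", {
    f <- rbind(matrix(0, 20, 3), matrix(5, 20, 3))
    rownames(f) <- sprintf("s%02d", 1:40)
    cc <- consensusCluster(f, k = 2, reps = 100, seed = 1L)
    cons <- consensusMatrix(cc)
    truth <- rep(1:2, each = 20)
    same <- outer(truth, truth, "==")
    # co-sampled pairs of the same mass always co-cluster; never across
    expect_true(all(cons[same] %in% c(0, 1)))  # 0 only if never co-sampled
    expect_true(all(cons[upper.tri(cons) & same] > 0.3))
    expect_true(all(cons[!same] == 0))
    expect_equal(ari(clusterLabels(cc), truth), 1)
    expect_equal(pacScore(cc), 0)
})

test_that("consensus clustering recovers well-separated Gaussian blobs", {
    set.seed(5)
    f <- rbind(matrix(rnorm(50 * 4, 0), 50, 4), matrix(rnorm(50 * 4, 6), 50, 4))
    rownames(f) <- sprintf("s%03d", 1:100)
    cc <- consensusCluster(f, k = 2, reps = 200, seed = 2L)
    expect_gte(ari(clusterLabels(cc), rep(1:2, each = 50)), 0.99)
    # determinism under seed
    cc2 <- consensusCluster(f, k = 2, reps = 200, seed = 2L)
    expect_identical(clusterLabels(cc), clusterLabels(cc2))
    expect_equal(consensusMatrix(cc), consensusMatrix(cc2))
    # input validation
    expect_error(consensusCluster(f, k = 1), "k must")
    expect_error(consensusCluster(f, k = 60), "k must")
})

test_that("consensus matrix entries are proportions and PAC stabilizes with reps", {
    set.seed(9)
    f <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(sprintf("s%02d", 1:60)))
    pacAt <- function(reps, seeds) vapply(seeds, function(s)
        pacScore(consensusCluster(f, k = 2, reps = reps, seed = s)),
        numeric(1))
    p50 <- pacAt(50, 1:8)
    p500 <- pacAt(500, 1:8)
    expect_true(all(p50 >= 0 & p50 <= 1))
    expect_lt(stats::var(p500), stats::var(p50))
})

test_that("two-step classifier recovers a planted 4-subtype cohort", {
    bk <- genBulkCohort(bulkSimConfig(nSamples = 200, plantSubtypes = TRUE,
                                      seed = 5L))
    lab <- twoStepSubtype(bk$fractions, bk$expr, bk$earlySignatureGenes,
                          seed = 9L, reps = 200)
    # partition: every sample labeled exactly once
    expect_equal(sort(names(lab)), sort(sampleIds(bk$fractions)))
    expect_true(all(lab %in% c("A1", "A2", "A3", "B")))
    perms <- function(v) if (length(v) == 1) list(v) else
        do.call(c, lapply(seq_along(v), function(i)
            lapply(perms(v[-i]), function(p) c(v[i], p))))
    best <- max(vapply(perms(c("A1", "A2", "A3", "B")), function(p) {
        m <- stats::setNames(p, c("A1", "A2", "A3", "B"))
        mean(m[lab] == bk$subtypeLabels[names(lab)])
    }, numeric(1)))
    expect_gte(best, 0.9)
    # A1 has the highest effector infiltration by construction of the naming
    eff <- rowSums(fractionValues(bk$fractions)[, c("Macrophages.M1",
        "T.cells.CD8", "T.cells.CD4.memory.activated")])
    expect_gt(mean(eff[lab == "A1"]), mean(eff[lab == "A3"]))
    expect_gt(mean(eff[lab == "A3"]), mean(eff[lab == "B"]))
})

test_that("two-step classifier rejects degenerate input", {
    F <- matrix(1 / 4, 30, 4, dimnames = list(sprintf("s%02d", 1:30),
        c("Macrophages.M1", "T.cells.CD8",
          "T.cells.CD4.memory.activated", "Other")))
    e <- makeExpr(matrix(rexp(10 * 30), 10), cells = rownames(F))
    expect_error(twoStepSubtype(CellFractions(F), e,
                                geneIds(e)[1:3], reps = 20),
                 "zero-variance")
})

test_that("logrank is zero on identical groups and matches the risk-table oracle", {
    surv <- data.frame(sample = sprintf("s%d", 1:10),
                       time = rep(c(2, 4, 5, 7, 9), 2),
                       event = rep(c(1, 1, 0, 1, 0), 2))
    lab <- stats::setNames(rep(c("a", "b"), each = 5), surv$sample)
    res <- logrank(surv, lab)
    expect_equal(res$chiSquare, 0)
    expect_equal(res$pValue, 1)

    # 10-sample worked fixture vs explicit risk-table computation
    surv2 <- data.frame(sample = sprintf("s%d", 1:10),
                        time = c(1, 3, 4, 6, 8, 2, 5, 7, 9, 11),
                        event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0))
    lab2 <- stats::setNames(rep(c("a", "b"), each = 5), surv2$sample)
    res2 <- logrank(surv2, lab2)
    want <- oracleLogrank(surv2$time, surv2$event,
                          rep(c("a", "b"), each = 5))
    expect_equal(res2$chiSquare, want, tolerance = 1e-10)
    # swapping group labels leaves the statistic unchanged
    flipped <- stats::setNames(ifelse(lab2 == "a", "b", "a"), names(lab2))
    expect_equal(logrank(surv2, flipped)$chiSquare, res2$chiSquare)
    # KM table is a valid step function
    expect_true(all(diff(res2$km$survival[res2$km$group == "a"]) <= 0))
})

test_that("logrank detects a planted hazard ratio and validates input", {
    set.seed(31)
    t1 <- rexp(100, 0.3); t2 <- rexp(100, 0.1)
    surv <- data.frame(sample = sprintf("s%d", 1:200),
                       time = c(t1, t2), event = 1)
    lab <- stats::setNames(rep(c("a", "b"), each = 100), surv$sample)
    expect_lt(logrank(surv, lab)$pValue, 0.01)
    expect_error(logrank(surv, stats::setNames(rep("a", 200), surv$sample)),
                 "two non-empty groups")
    expect_error(logrank(transform(surv, time = -time), lab), "positive")
})
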