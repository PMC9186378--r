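test_that("feature assembly validates its inputs and reflects the phenotype", {
    bk <- genBulkCohort(bulkSimConfig(nSamples = 60, nGenes = 150, seed = 6L))
    ft <- buildFeatures(bk$expr, bk$fractions, bk$response)
    expect_equal(ncol(ft$features), 7)
    expect_equal(colnames(ft$features)[1:4],
                 c("CXCL9", "CXCL10", "CXCL11", "CCL5"))
    # z-scored columns
    expect_lt(max(abs(colMeans(ft$features))), 1e-12)
    expect_equal(unname(apply(ft$features, 2, sd)), rep(1, 7))
    # hot samples carry higher chemokine features
    hot <- bk$hotLabels[rownames(ft$features)] == "hot"
    expect_gt(mean(ft$features[hot, 1:4]), mean(ft$features[!hot, 1:4]))

    # missing sample in fractions
    Fsub <- fractionValues(bk$fractions)[-1, ]
    expect_error(buildFeatures(bk$expr, CellFractions(Fsub), bk$response),
                 "missing from fractions")
    # missing cell-type column named
    Fdrop <- fractionValues(bk$fractions)
    Fdrop <- Fdrop[, colnames(Fdrop) != "T.cells.CD8"]
    Fdrop <- Fdrop / rowSums(Fdrop)
    expect_error(buildFeatures(bk$expr, CellFractions(Fdrop), bk$response),
                 "T.cells.CD8")
    # constant feature rejected with a hint
    Fconst <- fractionValues(bk$fractions)
    Fconst[, "Macrophages.M1"] <- 0
    Fconst <- Fconst / rowSums(Fconst)
    expect_error(buildFeatures(bk$expr, CellFractions(Fconst), bk$response),
                 "constant feature")
})

test_that("analytic gradients match central finite differences", {
    set.seed(2)
    X <- matrix(rnorm(12 * 7), 12, 7,
                dimnames = list(sprintf("s%02d", 1:12), letters[1:7]))
    y <- rep(c(0, 1), 6)
    sizes <- c(7, 20, 5, 1)
    ws <- lapply(1:3, function(l)
        matrix(runif(sizes[l + 1] * sizes[l], -0.5, 0.5),
               sizes[l + 1], sizes[l]))
    bs <- lapply(1:3, function(l) runif(sizes[l + 1], -0.5, 0.5))
    g <- mlpLossGrad(ws, bs, X, y)
    eps <- 1e-5
    maxrel <- 0
    for (l in 1:3) {
        for (i in seq_along(ws[[l]])) {
            wp <- ws; wp[[l]][i] <- wp[[l]][i] + eps
            wm <- ws; wm[[l]][i] <- wm[[l]][i] - eps
            fd <- (mlpLossGrad(wp, bs, X, y)$loss -
                   mlpLossGrad(wm, bs, X, y)$loss) / (2 * eps)
            maxrel <- max(maxrel, abs(fd - g$gradWeights[[l]][i]) /
                                  max(abs(fd), 1e-8))
        }
        for (i in seq_along(bs[[l]])) {
            bp <- bs; bp[[l]][i] <- bp[[l]][i] + eps
            bm <- bs; bm[[l]][i] <- bm[[l]][i] - eps
            fd <- (mlpLossGrad(ws, bp, X, y)$loss -
                   mlpLossGrad(ws, bm, X, y)$loss) / (2 * eps)
            maxrel <- max(maxrel, abs(fd - g$gradBiases[[l]][i]) /
                                  max(abs(fd), 1e-8))
        }
    }
    expect_lt(maxrel, 1e-4)
})

test_that("training is deterministic, loss decreases, and separable data fit", {
    bk <- genBulkCohort(bulkSimConfig(nSamples = 200,
        responseCoefficients = c(0, 3, 3, 3, 3, 2, 2, 2), seed = 6L))
    ft <- buildFeatures(bk$expr, bk$fractions, bk$response)
    m1 <- trainMlp(ft, seed = 11L)
    m2 <- trainMlp(ft, seed = 11L)
    expect_identical(m1@weights, m2@weights)
    expect_identical(m1@biases, m2@biases)
    auc <- evaluateRoc(predictMlp(m1, ft), ft$response)$auc
    expect_gte(auc, 0.95)
    # with dropout off and a small lr the loss trace is non-increasing
    m0 <- trainMlp(ft, lr = 0.005, epochs = 300, dropoutRate = 0, seed = 3L)
    expect_true(all(diff(m0@training$lossTrace) <= 1e-12))
    # contract errors
    bad <- ft; bad$response[] <- 1
    expect_error(trainMlp(bad), "both response classes")
    small <- ft
    small$features <- ft$features[1:10, ]; small$response <- ft$response[1:10]
    expect_error(trainMlp(small), ">= 20 samples")
})

test_that("prediction follows the sigmoid network structure", {
    sizes <- c(7L, 20L, 5L, 1L)
    zeroW <- lapply(1:3, function(l) matrix(0, sizes[l + 1], sizes[l]))
    zeroB <- lapply(1:3, function(l) rep(0, sizes[l + 1]))
    m <- new("MlpModel", layerSizes = sizes, weights = zeroW, biases = zeroB,
             dropoutRate = 0, featureNames = letters[1:7],
             featureCenter = rep(0, 7), featureScale = rep(1, 7),
             training = list())
    X <- matrix(rnorm(5 * 7), 5, 7,
                dimnames = list(sprintf("s%d", 1:5), letters[1:7]))
    expect_equal(unname(predictMlp(m, X)), rep(0.5, 5))

    # all-non-negative weights: output is monotone in every input
    posW <- lapply(1:3, function(l)
        matrix(0.2, sizes[l + 1], sizes[l]))
    mp <- new("MlpModel", layerSizes = sizes, weights = posW, biases = zeroB,
              dropoutRate = 0, featureNames = letters[1:7],
              featureCenter = rep(0, 7), featureScale = rep(1, 7),
              training = list())
    x0 <- matrix(0, 1, 7, dimnames = list("s", letters[1:7]))
    x1 <- x0; x1[1, 3] <- 2
    expect_gte(predictMlp(mp, x1), predictMlp(mp, x0))
    # schema mismatch is named
    colnames(x0) <- LETTERS[1:7]
    expect_error(predictMlp(mp, x0), "schema mismatch")
})

test_that("model JSON serialization round-trips bit-exactly", {
    bk <- genBulkCohort(bulkSimConfig(nSamples = 40, nGenes = 120, seed = 9L))
    ft <- buildFeatures(bk$expr, bk$fractions, bk$response)
    m <- trainMlp(ft, epochs = 50, seed = 2L)
    p1 <- predictMlp(m, ft)
    path <- tempfile(fileext = ".json")
    saveMlpModel(m, path)
    m2 <- loadMlpModel(path)
    expect_identical(m2@weights, m@weights)
    expect_identical(m2@biases, m@biases)
    expect_identical(predictMlp(m2, ft), p1)
})

test_that("ROC evaluation matches exhaustive pair counting", {
    # perfect separation
    p <- c(0.9, 0.8, 0.2, 0.1); y <- c(1, 1, 0, 0)
    ev <- evaluateRoc(p, y)
    expect_equal(ev$auc, 1)
    expect_true(all(diff(ev$tpr) >= 0) && all(diff(ev$fpr) >= 0))
    # 8-sample fixtures with ties vs brute-force pair counting
    set.seed(88)
    for (i in 1:25) {
        p <- sample(seq(0, 1, 0.25), 8, replace = TRUE)
        y <- c(0, 1, sample(0:1, 6, replace = TRUE))
        expect_equal(evaluateRoc(p, y)$auc, oracleAuc(p, y),
                     tolerance = 1e-12)
    }
    # AUC is invariant to strictly monotone transforms
    p2 <- c(0.05, 0.6, 0.3, 0.9, 0.2, 0.7); y2 <- c(0, 1, 0, 1, 1, 0)
    expect_equal(evaluateRoc(plogis(5 * p2), y2)$auc,
                 evaluateRoc(p2, y2)$auc)
    # null probabilities give AUC near 1/2
    set.seed(3)
    pn <- runif(1000); yn <- rbinom(1000, 1, 0.5)
    expect_lt(abs(evaluateRoc(pn, yn)$auc - 0.5), 0.05)
    # confusion matrix at 0.5
    cm <- evaluateRoc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))$confusion
    expect_equal(as.vector(cm), c(1, 1, 1, 1))
    expect_error(evaluateRoc(c(0.2, 0.8), c(1, 1)), "both classes")
})

test_that("ROC agrees with an independent package implementation", {
    set.seed(10)
    p <- runif(60); y <- rbinom(60, 1, plogis(3 * (p - 0.5)))
    if (length(unique(y)) < 2) y[1:2] <- 0:1
    want <- as.numeric(suppressMessages(pROC::auc(y, p)))
    expect_equal(evaluateRoc(p, y)$auc, want, tolerance = 1e-10)
})
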